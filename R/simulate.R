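# Single-cell dynamics of the surrogate whole-cell model.
#
# The cell couples three layers: transcription (gene copy number x binding
# probability x k_txn), first-order RNA decay (half-life), translation
# (k_tl x RNA), saturable metabolic fluxes (kcat x enzyme x S/(K+S)) and a
# growth law that multiplies mass by (1 + mu*dt) with mu proportional to the
# clamped geometric mean of fluxes normalized by their wild-type birth values.
# Replication initiates at a mass threshold, forks run bidirectionally, and
# cytokinesis requires completed replication plus doubled mass.

# initial state: RNA at the c = 1 birth-death steady state, protein at
# k_tl * RNA0 * tau_p, metabolites at the set point
init_state <- function(spec, params, deterministic) {
  cst <- spec$constants
  p  <- param_values(params, "binding_probability")
  th <- param_values(params, "rna_half_life")
  lambda <- log(2) / th
  rna0 <- p * cst$k_txn / lambda
  prot0 <- cst$k_tl * rna0 * cst$tau_p
  if (!deterministic) {
    rna0 <- stats::rpois(length(rna0), rna0)
    prot0 <- stats::rpois(length(prot0), prot0)
  }
  list(rna = unname(rna0), protein = unname(prot0),
       S = rep(cst$S_star, spec$n_metabolites), mass = cst$initial_mass)
}

#' Simulate a single surrogate cell over one life cycle
#'
#' Advances the cell in fixed steps `dt` from birth to cytokinesis (or to
#' `max_time`, in which case the trajectory carries `timeout = TRUE`). In
#' deterministic mode all molecular updates use their expected values, so the
#' trajectory is a smooth function of the parameters; in stochastic mode
#' transcription and translation are Poisson events, RNA decay is binomial
#' survival, and the initial molecule counts are Poisson draws.
#'
#' @param spec a [cell_model_spec].
#' @param params a [param_set] consistent with `spec`.
#' @param seed integer seed (ignored in deterministic mode).
#' @param mode `"stochastic"` or `"deterministic"`.
#' @return an object of class `cell_trajectory`: time grid (last point is the
#'   interpolated cytokinesis time), per-time mass, volume and instantaneous
#'   growth rate, per-gene RNA/protein/copy-number matrices, per-reaction flux
#'   and per-metabolite concentration matrices, lifetime transcription
#'   initiation counts (`chip`, the ChIP-seq analogue), and the event times
#'   `t_initiation <= t_completion <= t_cytokinesis`.
#' @export
simulate_cell <- function(spec, params, seed = NULL,
                          mode = c("stochastic", "deterministic")) {
  mode <- match.arg(mode)
  det <- mode == "deterministic"
  validate_param_set(params)
  if (!identical(sort(params$name), sort(spec$wildtype$name)))
    stop("invalid parameter: names do not match the model specification")
  if (!det && !is.null(seed)) set.seed(as.integer(seed %% 2147483647))

  cst <- spec$constants
  G <- spec$n_genes; R <- spec$n_reactions; Mm <- spec$n_metabolites
  p    <- unname(param_values(params, "binding_probability")[paste0("p_", spec$gene_names)])
  th   <- unname(param_values(params, "rna_half_life")[paste0("thalf_", spec$gene_names)])
  kcat <- unname(param_values(params, "turnover_number")[paste0("kcat_", spec$reaction_names)])
  lambda <- log(2) / th
  d_gene <- pmin(spec$gene_positions, 1 - spec$gene_positions)  # distance from oriC
  mg <- spec$metabolic_genes
  mor <- spec$met_of_reaction
  ref_flux <- spec$constants$ref_flux
  # metabolite <- reaction aggregation matrix; phi = A %*% flux / mass
  Amat <- 1 * outer(seq_len(Mm), mor, "==")
  phi_ref <- as.numeric(Amat %*% ref_flux) / cst$initial_mass

  st <- init_state(spec, params, det)
  dt <- cst$dt
  n_max <- ceiling(cst$max_time / dt) + 8L  # slack for float accumulation
  tgrid <- mass_v <- mu_v <- numeric(n_max)
  rna_m <- prot_m <- copy_m <- matrix(0, n_max, G)
  flux_m <- matrix(0, n_max, R); met_m <- matrix(0, n_max, Mm)
  chip <- numeric(G)

  t_init <- t_comp <- t_div <- NA_real_
  initiated <- completed <- divided <- FALSE
  t <- 0; k <- 0L
  relax <- function(h) 1 - exp(-cst$k_relax * h)

  repeat {
    k <- k + 1L
    # gene copy number from fork progress (forks symmetric, speed per fork)
    if (initiated) {
      fork <- cst$fork_speed * (t - t_init)
      cn <- 1 + as.numeric(fork >= d_gene)
    } else cn <- rep(1, G)

    # record state at time t
    sat_now <- st$S[mor] / (cst$K + st$S[mor])
    v_now <- kcat * st$protein[mg] * sat_now
    ratio <- pmin(pmax(v_now / ref_flux, cst$ratio_floor), cst$ratio_cap)
    mu <- cst$mu0 * exp(mean(log(ratio)))
    tgrid[k] <- t; mass_v[k] <- st$mass; mu_v[k] <- mu
    rna_m[k, ] <- st$rna; prot_m[k, ] <- st$protein; copy_m[k, ] <- cn
    flux_m[k, ] <- v_now; met_m[k, ] <- st$S

    if (divided || t >= cst$max_time) break

    # step length: shorten the final step to land exactly on cytokinesis
    h <- dt

    # --- replication / division events within [t, t + h] ---------------------
    mass_next <- st$mass * (1 + mu * h)
    if (!initiated && mass_next >= cst$repl_mass * cst$initial_mass) {
      frac <- (cst$repl_mass * cst$initial_mass - st$mass) / (mass_next - st$mass)
      t_init <- t + h * max(0, min(1, frac))
      initiated <- TRUE
    }
    if (initiated && !completed) {
      tc <- t_init + 0.5 / cst$fork_speed
      if (tc <= t + h) { t_comp <- tc; completed <- TRUE }
    }
    if (completed) {
      t2 <- NA_real_
      if (mass_next >= 2 * cst$initial_mass) {
        frac <- (2 * cst$initial_mass - st$mass) / (mass_next - st$mass)
        t2 <- t + h * max(0, min(1, frac))
      }
      cand <- max(t_comp, t2)
      if (!is.na(cand) && cand <= t + h) {
        t_div <- max(cand, t)            # cytokinesis time, divide there
        h <- t_div - t
        divided <- TRUE
        if (h <= 0) { h <- 1e-12 }
      }
    }

    # --- molecular updates over step of length h -----------------------------
    # fractional copy coverage for genes the fork passes during this step
    if (initiated) {
      tp <- t_init + d_gene / cst$fork_speed   # fork passage time per gene
      cover <- pmin(pmax((t + h - tp) / h, 0), 1)
    } else cover <- rep(0, G)
    c_eff <- 1 + cover
    syn_rate <- c_eff * p * cst$k_txn
    surv <- exp(-lambda * h)
    if (det) {
      chip <- chip + syn_rate * h
      st$rna <- st$rna * surv + syn_rate / lambda * (1 - surv)
      st$protein <- st$protein + cst$k_tl * st$rna * h
    } else {
      events <- stats::rpois(G, syn_rate * h)
      chip <- chip + events
      st$rna <- stats::rbinom(G, st$rna, surv) + events
      st$protein <- st$protein + stats::rpois(G, cst$k_tl * st$rna * h)
    }
    # metabolite pools relax toward a flux-coupled homeostatic target
    phi <- as.numeric(Amat %*% v_now) / st$mass
    target <- cst$S_star * (phi / phi_ref)^cst$gamma_met
    st$S <- st$S + relax(h) * (target - st$S)
    st$mass <- st$mass * (1 + mu * h)
    t <- t + h
  }

  idx <- seq_len(k)
  structure(list(
    time = tgrid[idx], mass = mass_v[idx], volume = mass_v[idx],
    growth_rate = mu_v[idx],
    rna = rna_m[idx, , drop = FALSE], protein = prot_m[idx, , drop = FALSE],
    copy = copy_m[idx, , drop = FALSE], flux = flux_m[idx, , drop = FALSE],
    metabolites = met_m[idx, , drop = FALSE], chip = chip,
    events = list(t_initiation = t_init, t_completion = t_comp,
                  t_cytokinesis = t_div),
    divided = divided, timeout = !divided,
    mode = mode, gene_names = spec$gene_names,
    reaction_names = spec$reaction_names
  ), class = "cell_trajectory")
}

#' @export
print.cell_trajectory <- function(x, ...) {
  cat(sprintf("<cell_trajectory> %s, %d steps, %s\n", x$mode, length(x$time),
              if (x$divided) sprintf("divided at t = %.4f", x$events$t_cytokinesis)
              else "timeout (no division)"))
  invisible(x)
}

# trapezoidal time average of a vector (one series) or matrix (series in
# columns) sampled on the given time grid
time_average <- function(time, y) {
  y <- as.matrix(y)
  n <- length(time)
  if (n < 2) return(as.numeric(colMeans(y)))
  w <- diff(time)
  num <- colSums((y[-n, , drop = FALSE] + y[-1, , drop = FALSE]) / 2 * w)
  as.numeric(num / (time[n] - time[1]))
}

#' Mean doubling time of divided cells
#'
#' @param x a `cell_trajectory`, a list of them, or a [data_bundle] carrying
#'   the cytokinesis-time measurement.
#' @return mean cytokinesis time across divided cells, with attribute
#'   `n_undivided` counting excluded cells (a warning is raised when any cell
#'   failed to divide).
#' @export
doubling_time <- function(x) {
  if (inherits(x, "cell_trajectory")) x <- list(x)
  if (inherits(x, "data_bundle")) {
    i <- which(x$registry$data_class == "single_cell" &
                 x$registry$entity == "t_cytokinesis")
    if (!length(i)) stop("bundle carries no cytokinesis-time measurement")
    out <- x$mean[i]
    attr(out, "n_undivided") <- x$n_undivided %||% 0L
    return(out)
  }
  tt <- vapply(x, function(tr) tr$events$t_cytokinesis, 0.0)
  div <- !is.na(tt)
  if (!any(div)) stop("doubling time undefined: no cell divided")
  out <- mean(tt[div])
  attr(out, "n_undivided") <- sum(!div)
  if (any(!div))
    warning(sprintf("%d of %d cells did not divide and were excluded",
                    sum(!div), length(tt)))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
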