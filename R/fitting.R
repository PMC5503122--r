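#' Fit configuration
#'
#' Controls for the nonlinear conjugate-gradient optimisation of `R0`
#' parameters: convergence is declared when the largest gradient component
#' of the squared-deviation objective falls below `gradient_tolerance`;
#' between converged passes, sites whose bond-valence sum leaves the
#' `(0, 2S)` window under the current parameters are pruned and the
#' optimiser restarts.
#'
#' @param gradient_tolerance Convergence threshold on `max |d sigma^2/d R0|`.
#' @param max_iterations Maximum conjugate-gradient iterations per pass.
#' @param restart_pruning Apply in-loop window pruning between passes.
#' @param max_prune_passes Cap on prune-and-restart passes.
#' @param min_separation Minimum Gaussian-mixture mean separation (valence
#'   units) below which [split_bimodal()] declines to split.
#' @param seed Seed for any stochastic subroutine (the optimiser itself is
#'   deterministic; recorded for the manifest).
#' @return An object of class `bv_fit_config`.
#' @export
fit_config <- function(gradient_tolerance = 1e-8,
                       max_iterations = 10000L,
                       restart_pruning = TRUE,
                       max_prune_passes = 20L,
                       min_separation = 0.3,
                       seed = 1L) {
  stopifnot(gradient_tolerance > 0, max_iterations >= 1,
            max_prune_passes >= 1, min_separation >= 0)
  structure(list(
    gradient_tolerance = gradient_tolerance,
    max_iterations = as.integer(max_iterations),
    restart_pruning = isTRUE(restart_pruning),
    max_prune_passes = as.integer(max_prune_passes),
    min_separation = min_separation,
    line_search = "strong-Wolfe bracket/zoom (c1=1e-4, c2=0.1)",
    seed = as.integer(seed)
  ), class = "bv_fit_config")
}

# ---- compact population representation -----------------------------------
# Flattens a list of sites into parallel vectors so that one objective or
# gradient evaluation is a single vectorised pass: per contact the distance
# and an index into the fitted-parameter vector; per site the expected
# oxidation state.
index_population <- function(sites, params) {
  keys_by_site <- lapply(sites, site_contact_keys, params = params)
  all_keys <- sort(unique(unlist(keys_by_site)))
  missing <- setdiff(all_keys, names(params$entries))
  if (length(missing)) {
    stop("missing-parameter: no R0 for bond type(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  site_idx <- rep.int(seq_along(sites),
                      vapply(keys_by_site, length, 0L))
  list(
    keys = all_keys,
    r0 = vapply(all_keys, function(k) params$entries[[k]]$r0, 0),
    b = params$b,
    dist = unlist(lapply(sites, function(s) s$contacts$distance),
                  use.names = FALSE),
    key_id = match(unlist(keys_by_site, use.names = FALSE), all_keys),
    site_idx = site_idx,
    n_sites = length(sites),
    S = vapply(sites, function(s) as.numeric(s$oxidation), 0)
  )
}

# per-site bond-valence sums for a candidate r0 vector
pop_bvs <- function(pop, r0) {
  v <- exp((r0[pop$key_id] - pop$dist) / pop$b)
  V <- numeric(pop$n_sites)
  agg <- rowsum(v, pop$site_idx, reorder = FALSE)
  V[as.integer(rownames(agg))] <- agg[, 1L]
  V
}

pop_objective <- function(pop, r0) {
  sum((pop_bvs(pop, r0) - pop$S)^2)
}

pop_gradient <- function(pop, r0) {
  v <- exp((r0[pop$key_id] - pop$dist) / pop$b)
  V <- pop_bvs(pop, r0)
  resid <- (V - pop$S)[pop$site_idx]
  g <- numeric(length(r0))
  agg <- rowsum(resid * v, pop$key_id, reorder = FALSE)
  g[as.integer(rownames(agg))] <- agg[, 1L]
  (2 / pop$b) * g
}

#' Squared-deviation objective of a parameter set over sites
#'
#' `sigma^2 = sum_i (V_i - S_i)^2`: the summed squared deviation of each
#' site's bond-valence sum from its expected oxidation state. This is the
#' function minimised by [fit_r0()].
#'
#' @param params A `bv_params` resolving every bond type present.
#' @param sites List of curated, oxidation-assigned `bv_site`.
#' @return The objective value (valence units squared).
#' @export
bv_objective <- function(params, sites) {
  pop <- index_population(sites, params)
  pop_objective(pop, pop$r0)
}

#' Analytic gradient of the squared-deviation objective
#'
#' `d sigma^2 / d R0_beta = (2/b) * sum_i (V_i - S_i) * V_{i,beta}`, where
#' `V_{i,beta}` is the summed valence of the type-beta contacts of site i.
#' Bond types present in `params` but in no site get component zero.
#'
#' @inheritParams bv_objective
#' @return Named numeric vector over the bond types present in `sites`.
#' @export
bv_gradient <- function(params, sites) {
  pop <- index_population(sites, params)
  stats::setNames(pop_gradient(pop, pop$r0), pop$keys)
}

# ---- derivative-based line search ----------------------------------------
# "Exact-enough" minimisation of phi(t) = f(x + t d) along a descent
# direction: expand a bracket until phi'(t) changes sign, then secant/
# bisection on phi' until the strong curvature condition
# |phi'(t)| <= c2 |phi'(0)| holds. Working on the analytic derivative
# keeps the search accurate near the minimum, where differences of f
# itself fall below double-precision rounding.
line_search_dphi <- function(dphi, dphi0, t_init, c2 = 0.1,
                             max_expand = 60L, max_refine = 100L) {
  lo <- 0; dlo <- dphi0
  t <- t_init; dt <- dphi(t)
  k <- 0L
  while (dt < 0 && k < max_expand) {
    if (abs(dt) <= c2 * abs(dphi0)) return(t)
    lo <- t; dlo <- dt
    t <- 2 * t
    dt <- dphi(t)
    k <- k + 1L
  }
  if (dt < 0) return(t)  # objective keeps descending: take the long step
  hi <- t; dhi <- dt
  for (k in seq_len(max_refine)) {
    if (abs(dt) <= c2 * abs(dphi0)) return(t)
    t_sec <- if (dhi > dlo) lo - dlo * (hi - lo) / (dhi - dlo) else NA
    t <- if (is.finite(t_sec) && t_sec > lo && t_sec < hi) t_sec
         else 0.5 * (lo + hi)
    dt <- dphi(t)
    if (dt < 0) { lo <- t; dlo <- dt } else { hi <- t; dhi <- dt }
    if ((hi - lo) < 1e-18 * max(1, hi)) break
  }
  t
}

# Polak-Ribiere+ nonlinear conjugate gradients with steepest-descent
# restart on non-descent directions. Convergence on max |gradient|; a step
# too small to move the parameters ends the run (numerical floor).
cg_minimize <- function(pop, r0, tol, max_iter) {
  f <- pop_objective(pop, r0)
  g <- pop_gradient(pop, r0)
  d <- -g
  trace <- f
  iter <- 0L
  stalled <- FALSE
  while (max(abs(g)) > tol && iter < max_iter) {
    iter <- iter + 1L
    dphi0 <- sum(g * d)
    if (dphi0 >= 0) {  # not a descent direction: steepest-descent restart
      d <- -g
      dphi0 <- sum(g * d)
      if (dphi0 >= 0) { stalled <- TRUE; break }  # gradient numerically zero
    }
    # first trial step scaled to a ~1e-2 A parameter move
    t0 <- min(1, 0.01 / max(max(abs(d)), 1e-12))
    t <- line_search_dphi(
      dphi = function(t) sum(pop_gradient(pop, r0 + t * d) * d),
      dphi0 = dphi0, t_init = t0
    )
    if (t * max(abs(d)) < 1e-15) { stalled <- TRUE; break }
    r0_new <- r0 + t * d
    f_new <- pop_objective(pop, r0_new)
    if (f_new > f * (1 + 1e-12) + 1e-300) {
      # derivative search overshot (non-unimodal ray); bisect back
      ok <- FALSE
      for (h in seq_len(40L)) {
        t <- t / 2
        r0_new <- r0 + t * d
        f_new <- pop_objective(pop, r0_new)
        if (f_new <= f) { ok <- TRUE; break }
      }
      if (!ok) { stalled <- TRUE; break }
    }
    g_new <- pop_gradient(pop, r0_new)
    beta <- max(0, sum(g_new * (g_new - g)) / max(sum(g * g), 1e-300))
    d <- -g_new + beta * d
    r0 <- r0_new; f <- f_new; g <- g_new
    trace <- c(trace, f)
  }
  # a stall at the double-precision floor of the gradient still counts as
  # converged when the gradient is tiny relative to the objective scale
  converged <- max(abs(g)) <= tol ||
    (stalled && max(abs(g)) <= 1e-7 * max(1, abs(f)))
  list(r0 = r0, objective = f, gradient = g, trace = trace,
       iterations = iter, converged = converged)
}

#' Fit R0 parameters over homoleptic and heteroleptic sites
#'
#' Minimises the squared deviation of bond-valence sums around the expected
#' oxidation states, `sigma^2 = sum_i (V_i - S_i)^2`, simultaneously over
#' all bond types of one metal species, by nonlinear conjugate gradients
#' (Polak-Ribiere+ with steepest-descent restart and a strong-Wolfe line
#' search) starting from the supplied (typically literature) values.
#' Because heteroleptic sites couple several `R0` parameters through their
#' sums, this recovers parameters that the classical homoleptic closed form
#' cannot reach.
#'
#' After each converged pass, sites whose sum falls outside
#' `(0, 2S)` under the *current* parameters are pruned and the optimisation
#' restarts, until no site is removed (window pruning, configurable).
#'
#' @param sites List of curated `bv_site` sharing one metal species.
#' @param initial `bv_params` holding starting `R0` values for every bond
#'   type present in `sites` (plus the global `b`).
#' @param config A [fit_config()].
#' @param filter_config Optional [filter_config()]; only its
#'   `bvs_window_multiplier` is consulted for pruning.
#' @return An object of class `bv_fit`: `params` (converged `bv_params`
#'   with per-type uncertainties and site counts), `objective`,
#'   `objective_trace` (non-increasing over accepted steps, one block per
#'   pass), `pruned_sites` (ledger data.frame), `uncertainty` (named
#'   vector), `n_sites_used`, `sites` (the kept sites), `passes`,
#'   `converged`.
#' @export
fit_r0 <- function(sites, initial, config = fit_config(),
                   filter_config = NULL) {
  stopifnot(inherits(initial, "bv_params"), length(sites) >= 1)
  metal <- unique(vapply(sites, function(s) s$metal, ""))
  ox <- unique(vapply(sites, function(s) s$oxidation, 0L))
  if (length(metal) != 1L || length(unique(ox)) != 1L) {
    stop("fit_r0 expects sites of a single metal species (one element, ",
         "one oxidation state); got ",
         paste(metal, collapse = "/"), " with states ",
         paste(ox, collapse = "/"), call. = FALSE)
  }
  mult <- if (!is.null(filter_config)) filter_config$bvs_window_multiplier else 2.0
  ledger <- data.frame(entry_id = character(), site_id = character(),
                       pass = integer(), reason = character(),
                       stringsAsFactors = FALSE)
  trace <- numeric(0)
  pass <- 0L
  repeat {
    pass <- pass + 1L
    pop <- index_population(sites, initial)
    res <- cg_minimize(pop, pop$r0, config$gradient_tolerance,
                       config$max_iterations)
    trace <- c(trace, res$trace)
    for (k in seq_along(pop$keys)) {
      initial <- set_param(initial, pop$keys[k], res$r0[k])
    }
    if (!res$converged) {
      stop("fit_r0 did not converge within ", config$max_iterations,
           " iterations (max |grad| = ", signif(max(abs(res$gradient)), 3),
           "); best objective ", signif(res$objective, 6), call. = FALSE)
    }
    if (!config$restart_pruning || pass >= config$max_prune_passes) break
    V <- pop_bvs(pop, res$r0)
    S <- pop$S
    bad <- which(V <= 0 | V >= mult * S)
    if (!length(bad)) break
    ledger <- rbind(ledger, data.frame(
      entry_id = vapply(sites[bad], function(s) s$entry_id, ""),
      site_id = vapply(sites[bad], function(s) s$site_id, ""),
      pass = pass, reason = "bvs-window",
      stringsAsFactors = FALSE
    ))
    sites <- sites[-bad]
    if (!length(sites)) {
      stop("window pruning removed every site", call. = FALSE)
    }
  }
  pop <- index_population(sites, initial)
  lost <- setdiff(names(initial$entries), pop$keys)
  # count sites per type and attach uncertainties
  n_used <- vapply(pop$keys, function(k) {
    kid <- match(k, pop$keys)
    length(unique(pop$site_idx[pop$key_id == kid]))
  }, 0L)
  unc <- bv_uncertainty(sites, initial)
  for (k in pop$keys) {
    e <- initial$entries[[k]]
    initial$entries[[k]]$uncertainty <- unname(unc[k])
    initial$entries[[k]]$n_sites <- unname(n_used[k])
  }
  structure(list(
    params = initial,
    fitted_keys = pop$keys,
    objective = pop_objective(pop, pop$r0),
    objective_trace = trace,
    pruned_sites = ledger,
    uncertainty = unc,
    n_sites_used = n_used,
    sites = sites,
    passes = pass,
    converged = TRUE,
    keys_without_sites = lost
  ), class = "bv_fit")
}

#' @export
print.bv_fit <- function(x, ...) {
  cat("<bv_fit>", length(x$n_sites_used), "bond types,",
      length(x$sites), "sites, objective", signif(x$objective, 6),
      "after", x$passes, "pass(es),", nrow(x$pruned_sites), "pruned\n")
  print(as.data.frame(x$params), ...)
  invisible(x)
}

#' Per-type uncertainty as the root mean squared parameter shift
#'
#' For each bond type beta, the square root of the mean over sites
#' containing beta of `delta_r0(site, params, beta)^2` - the shift in that
#' one parameter that would make each site obey the sum rule exactly. This
#' bounds the parameter standard deviation from above (it can never be
#' smaller than the spread of per-site homoleptic `R0` values, absent
#' numerical compensation). Sites for which no feasible shift exists are
#' skipped and counted in the `n_skipped` attribute.
#'
#' @param sites List of curated `bv_site`.
#' @param params Fitted `bv_params`.
#' @return Named numeric vector of uncertainties in Angstrom (`NA` for a
#'   type with no feasible site), with attribute `n_skipped`.
#' @export
bv_uncertainty <- function(sites, params) {
  pop <- index_population(sites, params)
  out <- stats::setNames(rep(NA_real_, length(pop$keys)), pop$keys)
  skipped <- stats::setNames(integer(length(pop$keys)), pop$keys)
  for (k in seq_along(pop$keys)) {
    key <- pop$keys[k]
    holders <- unique(pop$site_idx[pop$key_id == k])
    shifts <- numeric(0)
    for (i in holders) {
      d <- tryCatch(delta_r0(sites[[i]], params, key), error = function(e) NA)
      if (is.na(d)) skipped[k] <- skipped[k] + 1L else shifts <- c(shifts, d)
    }
    if (length(shifts)) out[k] <- sqrt(mean(shifts^2))
  }
  attr(out, "n_skipped") <- skipped
  out
}

#' Per-type homoleptic summary (classical route)
#'
#' The traditional estimate: mean and standard deviation of the closed-form
#' per-site `R0` over homoleptic sites only, per bond type, with counts.
#' Sample standard deviation (n-1) is used; a single site reports sd 0.
#'
#' @param sites List of curated `bv_site`.
#' @param b Softness parameter in Angstrom.
#' @return data.frame with columns `key`, `mean_r0`, `sd_r0`, `n`.
#' @export
homoleptic_summary <- function(sites, b = 0.37) {
  homo <- Filter(function(s) is_homoleptic(s) && !is.na(s$oxidation), sites)
  if (!length(homo)) {
    return(data.frame(key = character(), mean_r0 = numeric(),
                      sd_r0 = numeric(), n = integer(),
                      stringsAsFactors = FALSE))
  }
  keys <- vapply(homo, function(s) {
    bond_type_key(s$metal, s$oxidation, s$contacts$ligand[1],
                  if (s$spin %in% c("LS", "HS")) s$spin else "none")
  }, "")
  r0s <- vapply(homo, homoleptic_r0, 0, b = b)
  out <- do.call(rbind, lapply(split(r0s, keys), function(v) {
    data.frame(mean_r0 = mean(v),
               sd_r0 = if (length(v) > 1L) stats::sd(v) else 0,
               n = length(v))
  }))
  out$key <- rownames(out)
  rownames(out) <- NULL
  out[, c("key", "mean_r0", "sd_r0", "n")]
}
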