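# Least-squares fitting of each architecture's free parameters to the
# multi-regime expression dataset: seeded Latin-hypercube multi-start in
# log10 parameter space with Nelder-Mead refinement. Model output and data
# are each normalised to unit maximum within a regime before residuals, so
# fits are free of the arbitrary microarray scale.

#' Default fitting bounds for an architecture
#'
#' Log-spaced box bounds for the multi-start search: `1e-3 .. 1e3` (a.u.)
#' for `v_max` and every half-saturation constant, `0.05 .. 5` per hour for
#' the degradation rate.
#'
#' @param arch A [cbf_architecture()].
#' @return A two-row matrix (`lower`, `upper`) with one column per free
#'   parameter (`v_max`, `K_<species>`..., `d`).
#' @export
default_bounds <- function(arch) {
  regs <- regulators(arch)
  nm <- c("v_max", paste0("K_", regs), "d")
  lower <- c(1e-3, rep(1e-3, length(regs)), 0.05)
  upper <- c(1e3, rep(1e3, length(regs)), 5)
  matrix(c(lower, upper), nrow = 2, byrow = TRUE,
         dimnames = list(c("lower", "upper"), nm))
}

# Latin-hypercube starting points drawn in seeded blocks of 8 rows, so the
# restart sequence for a given seed is nested: the first n rows are the
# same whatever n_restarts is, which makes the best cost non-increasing in
# the number of restarts.
lhs_starts <- function(n, npar, seed, block = 8L) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  m <- do.call(rbind, lapply(seq_len(ceiling(n / block)), function(b) {
    set.seed(((as.integer(seed) %% 1000003L) * 131L + b) %%
               .Machine$integer.max)
    lhs::randomLHS(block, npar)
  }))
  m[seq_len(n), , drop = FALSE]
}

theta_to_params <- function(theta, arch, hill_n = 2) {
  regs <- regulators(arch)
  v <- 10^theta[1]
  K <- setNames(10^theta[seq_along(regs) + 1], regs)
  d <- 10^theta[length(theta)]
  cbf_params(v, K, d, hill_n = hill_n)
}

# precompute, per regime: fine-grid species matrix, indices of the data
# times on the fine grid (offset by the entrainment transient), and the
# unit-max-normalised data values
build_fit_context <- function(dataset, clocks, internal_step = 0.05,
                              transient = 24) {
  stopifnot(inherits(dataset, "cbf_dataset") ||
              all(c("regime", "time_h", "expression") %in% names(dataset)))
  labels <- unique(dataset$regime)
  miss <- setdiff(labels, names(clocks))
  if (length(miss)) abort(paste0("No clock trajectory for regime(s): ",
                                 toString(miss)))
  ctx <- lapply(labels, function(lb) {
    dat <- dataset[dataset$regime == lb, ]
    span <- transient + max(dat$time_h)
    clk <- clocks[[lb]]
    if (max(clk$time_h) < span - 1e-9) {
      abort(paste0("Clock for ", lb, " must cover ", span,
                   " h (data span plus the ", transient, " h transient)."))
    }
    h <- internal_step
    tt <- seq(0, span, by = h)
    idx <- round((dat$time_h + transient) / h) + 1
    if (any(abs(tt[idx] - (dat$time_h + transient)) > 1e-6)) {
      abort("Data times must lie on the internal integration grid.")
    }
    ymax <- max(dat$expression)
    if (ymax <= 0) abort(paste0("All-zero data in regime ", lb))
    list(label = lb, species = clock_evaluator(clk)(tt), h = h, idx = idx,
         y_norm = dat$expression / ymax)
  })
  names(ctx) <- labels
  ctx
}

cost_from_context <- function(ctx, arch, params) {
  total <- 0
  for (rc in ctx) {
    p <- production_from_matrix(rc$species, arch, params)
    cc <- integrate_linear_decay(p, params$d, rc$h, p[1] / params$d)
    m <- cc[rc$idx]
    mx <- max(m)
    if (!is.finite(mx) || mx <= 0) {
      warn(paste0("Degenerate simulation for ", arch$label,
                  " in regime ", rc$label, "; infinite cost."))
      return(Inf)
    }
    total <- total + sum((m / mx - rc$y_norm)^2)
  }
  total
}

#' Normalised residual-sum-of-squares cost of a parameterised architecture
#'
#' Simulates the CBF3 submodel against each regime's clock trajectory
#' (discarding a 24-h entrainment transient), normalises both the simulated
#' mRNA and the data to unit maximum within the regime, and sums squared
#' residuals across all regimes and time points. A degenerate simulation
#' (non-finite or identically zero output) yields an infinite-cost sentinel
#' with a warning rather than an error.
#'
#' @param arch A [cbf_architecture()].
#' @param params A [cbf_params()].
#' @param dataset A `cbf_dataset` (columns `regime`, `time_h`,
#'   `expression`).
#' @param clocks Named list of `cbf_clock` trajectories, one per regime
#'   label, covering the data span plus the transient.
#' @param internal_step Integration step in hours (default 0.05).
#' @param transient Entrainment transient discarded before comparison,
#'   hours (default 24).
#' @return Non-negative cost (possibly `Inf`).
#' @export
rss_cost <- function(arch, params, dataset, clocks, internal_step = 0.05,
                     transient = 24) {
  ctx <- build_fit_context(dataset, clocks, internal_step, transient)
  cost_from_context(ctx, arch, params)
}

#' Fit one architecture to a multi-regime dataset
#'
#' Seeded multi-start least squares: starting points are drawn by Latin
#' hypercube sampling in log10 space within `bounds`, each start is refined
#' with derivative-free Nelder-Mead (soft box penalty, final clamp to
#' bounds), and the lowest-cost restart wins (ties broken by lowest restart
#' index). The whole procedure is deterministic for a fixed seed.
#'
#' @inheritParams rss_cost
#' @param n_restarts Number of multi-start restarts (default 24).
#' @param seed Integer seed for the restart sample.
#' @param bounds Two-row bounds matrix as from [default_bounds()].
#' @param hill_n Fixed Hill exponent (default 2).
#' @param maxit Nelder-Mead iteration cap per restart (default 300).
#' @return A `cbf_fit` object: architecture, best-fit [cbf_params()],
#'   `rss`, `n_points`, `k_free`, a per-restart `trace` tibble and the
#'   seed.
#' @examples
#' \donttest{
#' d <- generate_dataset(seed = 1)
#' clks <- lapply(standard_regimes(), simulate_clock)
#' fit <- fit_architecture(cbf_architecture("LHY_CCA1"), d, clks,
#'                         n_restarts = 4, seed = 1)
#' }
#' @export
fit_architecture <- function(arch, dataset, clocks, n_restarts = 24,
                             seed = 1, bounds = default_bounds(arch),
                             hill_n = 2, maxit = 300,
                             internal_step = 0.05, transient = 24) {
  stopifnot(inherits(arch, "cbf_architecture"))
  if (n_restarts < 1) abort("`n_restarts` must be at least 1.")
  if (any(!is.finite(bounds)) || any(bounds <= 0))
    abort("Bounds must be positive and finite.")
  ctx <- build_fit_context(dataset, clocks, internal_step, transient)
  lb <- log10(bounds["lower", ])
  ub <- log10(bounds["upper", ])
  npar <- length(lb)

  fn <- function(theta) {
    excess <- pmax(0, theta - ub) + pmax(0, lb - theta)
    pen <- 1e3 * sum(excess^2)
    params <- theta_to_params(pmin(pmax(theta, lb), ub), arch, hill_n)
    cost_from_context(ctx, arch, params) + pen
  }

  starts <- lhs_starts(n_restarts, npar, seed)
  starts <- sweep(sweep(starts, 2, ub - lb, `*`), 2, lb, `+`)

  results <- vector("list", n_restarts)
  for (i in seq_len(n_restarts)) {
    theta0 <- starts[i, ]
    # chained Nelder-Mead rounds: restarting the simplex from the current
    # optimum escapes the collapsed-simplex stagnation NM is prone to
    opt <- optim(theta0, fn, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-10))
    for (round in 1:5) {
      prev <- opt$value
      opt <- optim(opt$par, fn, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-12))
      if (prev - opt$value < 1e-12 * (1 + abs(prev))) break
    }
    theta <- pmin(pmax(opt$par, lb), ub)
    params <- theta_to_params(theta, arch, hill_n)
    results[[i]] <- list(cost = cost_from_context(ctx, arch, params),
                         start_cost = fn(theta0), params = params)
  }
  costs <- vapply(results, `[[`, 0, "cost")
  if (all(!is.finite(costs))) {
    abort(paste0("All restarts failed for architecture ", arch$label))
  }
  best <- which.min(costs)  # first minimum wins
  trace <- tibble(restart = seq_len(n_restarts),
                  start_cost = vapply(results, `[[`, 0, "start_cost"),
                  best_cost = costs)
  structure(list(arch = arch, params = results[[best]]$params,
                 rss = costs[best],
                 n_points = sum(vapply(ctx, function(r) length(r$idx), 0L)),
                 k_free = count_free_parameters(arch),
                 trace = trace, seed = seed, bounds = bounds),
            class = "cbf_fit")
}

#' @export
print.cbf_fit <- function(x, ...) {
  cat("<CBF3 fit ", x$arch$label, ">  rss = ", signif(x$rss, 5),
      "  n = ", x$n_points, "  k = ", x$k_free, "\n", sep = "")
  print(x$params)
  invisible(x)
}

#' Fit the whole architecture ensemble
#'
#' Fits every architecture in `ensemble` with [fit_architecture()], using a
#' per-architecture seed derived as `seed + position` so partial reruns are
#' reproducible.
#'
#' @inheritParams fit_architecture
#' @param ensemble Tibble from [cbf_ensemble()] (or a subset of its rows).
#' @param progress Print one line per architecture as it finishes.
#' @return Named list of `cbf_fit` objects, in ensemble order.
#' @export
fit_ensemble <- function(dataset, clocks, ensemble = cbf_ensemble(),
                         n_restarts = 24, seed = 1, hill_n = 2,
                         maxit = 300, internal_step = 0.05, transient = 24,
                         progress = FALSE) {
  fits <- purrr::imap(setNames(ensemble$arch, ensemble$label),
                      function(arch, lb) {
    i <- match(lb, ensemble$label)
    f <- fit_architecture(arch, dataset, clocks, n_restarts = n_restarts,
                          seed = seed + i, hill_n = hill_n, maxit = maxit,
                          internal_step = internal_step,
                          transient = transient)
    if (progress) message(sprintf("fitted %-28s rss = %.4f", lb, f$rss))
    f
  })
  fits
}

#' Tidy a CBF3 fit into a parameter table
#'
#' @param x A `cbf_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`.
#' @export
tidy.cbf_fit <- function(x, ...) {
  tibble(term = c("v_max", paste0("K_", names(x$params$K)), "d"),
         estimate = unname(c(x$params$v_max, x$params$K, x$params$d)))
}

#' One-row summary of a CBF3 fit
#'
#' @param x A `cbf_fit`.
#' @param ... Unused.
#' @return A tibble with `label`, `rss`, `n_points`, `k_free`, `aicc`.
#' @export
glance.cbf_fit <- function(x, ...) {
  tibble(label = x$arch$label, rss = x$rss, n_points = x$n_points,
         k_free = x$k_free, aicc = aicc(x$rss, x$n_points, x$k_free))
}

#' Serialise a fit to JSON
#' @param fit A `cbf_fit`.
#' @param path Optional path; if given the JSON is written there.
#' @return The JSON string, invisibly if written to `path`.
#' @export
fit_to_json <- function(fit, path = NULL) {
  x <- list(label = fit$arch$label,
            activators = fit$arch$activators,
            repressors = fit$arch$repressors,
            params = list(v_max = fit$params$v_max, K = as.list(fit$params$K),
                          d = fit$params$d, hill_n = fit$params$hill_n),
            rss = fit$rss, n_points = fit$n_points, k_free = fit$k_free,
            seed = fit$seed)
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
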