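## Model-to-data comparison: the nine-characteristic diagnostics panel,
## the difference metric over panels, normalized difference profiles, and
## derivative-free parameter fitting.

#' The nine diagnostic characteristics
#'
#' Names, in canonical order, of the nine summary characteristics entering
#' the model-to-data difference metric: global clustering `C`, mean path
#' length `P`, diameter `D`, assortativity `r`, hierarchy `beta`, Rent
#' exponent `p_T`, fractal dimension `d_B`, maximum modularity `Q`, and
#' number of communities `n_com`.
#'
#' @export
panel_characteristics <- function() {
  c("C", "P", "D", "r", "beta", "p_T", "d_B", "Q", "n_com")
}

#' Multiscale diagnostics panel of a network
#'
#' Computes the nine summary characteristics of a network together with
#' its degree-distribution summary and per-node scatters. Stochastic
#' sub-procedures (box-counting tilings, community-detection restarts,
#' min-cut bisection) consume R's global RNG; per-diagnostic dispersions
#' are recorded where the sub-procedure provides repetitions. Undefined
#' values (assortativity of a regular graph, scaling fits on graphs whose
#' diameter is too small) are flagged as `NA`, never zero-filled.
#'
#' @param g An undirected igraph object.
#' @param tilings Box-counting tilings (50 matches common practice at
#'   connectome scale; reduce for speed).
#' @param community_runs Louvain restarts; default 100.
#' @param resolution Modularity resolution \eqn{\gamma}; default 1.
#' @param min_part Smallest bisection part for Rentian scaling; default 8.
#' @return An object of class `diagnostics_panel`: a list with the nine
#'   characteristics, `degree` ([degree_stats()]), `profile`
#'   ([node_profile()]), `flags` (named reasons for undefined entries),
#'   and `provenance` (sub-procedure settings and dispersions).
#' @export
diagnostics_panel <- function(g, tilings = 50, community_runs = 100,
                              resolution = 1, min_part = 8) {
  check_graph(g)
  flags <- character(0)
  deg <- degree_stats(g)
  prof <- node_profile(g)
  pm <- path_metrics(g)
  r <- withCallingHandlers(
    assortativity_coef(g),
    warning = function(w) invokeRestart("muffleWarning"))
  if (is.na(r)) flags["r"] <- "undefined: zero endpoint-degree variance"
  beta <- tryCatch(hierarchy_exponent(prof)$exponent, error = function(e) {
    flags["beta"] <<- conditionMessage(e); NA_real_
  })
  fd <- tryCatch(fractal_dimension(g, tilings = tilings),
                 error = function(e) {
                   flags["d_B"] <<- conditionMessage(e); NULL
                 })
  rent <- tryCatch(rentian_scaling(g, min_part = min_part),
                   error = function(e) {
                     flags["p_T"] <<- conditionMessage(e); NULL
                   })
  com <- optimize_modularity(g, resolution = resolution,
                             runs = community_runs)
  out <- list(
    C = attr(prof, "global_clustering"),
    P = pm$mean_path,
    D = pm$diameter,
    r = r,
    beta = beta,
    p_T = if (is.null(rent)) NA_real_ else rent$fit$exponent,
    d_B = if (is.null(fd)) NA_real_ else fd$fit$exponent,
    Q = com$q_max,
    n_com = com$n_communities,
    degree = deg,
    profile = prof,
    flags = flags,
    provenance = list(
      tilings = tilings, community_runs = community_runs,
      resolution = resolution, min_part = min_part,
      component_fraction = pm$component_fraction,
      mean_communities = com$mean_communities,
      q_sd = sd(com$q_per_run),
      d_B_curve = if (is.null(fd)) NULL else fd$points,
      rent_curve = if (is.null(rent)) NULL else rent$curve)
  )
  class(out) <- "diagnostics_panel"
  out
}

#' @export
print.diagnostics_panel <- function(x, ...) {
  cat("Network diagnostics panel\n")
  vals <- vapply(panel_characteristics(), function(ch) x[[ch]], numeric(1))
  for (ch in panel_characteristics())
    cat(sprintf("  %-6s %s\n", ch,
                if (is.na(vals[ch])) paste0("undefined (", x$flags[ch], ")")
                else format(signif(vals[ch], 4))))
  cat(sprintf("  degree: mode %s (%d nodes), range %d-%d, density %.4f\n",
              paste(x$degree$mode_degree, collapse = " & "),
              x$degree$mode_count, x$degree$min_degree,
              x$degree$max_degree, x$degree$density))
  invisible(x)
}

## Internal: the nine characteristics of a panel as a named vector.
panel_values <- function(panel) {
  vapply(panel_characteristics(), function(ch) panel[[ch]], numeric(1))
}

#' Difference metric between two diagnostics panels
#'
#' The sum over the nine characteristics of the absolute relative
#' difference \eqn{\Delta = \sum_x |x_{model} - x_{data}| / |x_{data}|}.
#' All nine characteristics carry equal weight. The metric is asymmetric
#' (normalized by the data panel) and is a premetric: zero for identical
#' panels, nonnegative always. Undefined characteristics on either side
#' abort with an error naming them, rather than silently ranking
#' degenerate models well.
#'
#' @param model_panel,data_panel `diagnostics_panel` objects (or named
#'   lists/vectors containing the nine characteristics).
#' @return The difference \eqn{\Delta \ge 0}.
#' @export
panel_delta <- function(model_panel, data_panel) {
  xm <- if (inherits(model_panel, "diagnostics_panel"))
    panel_values(model_panel) else unlist(model_panel)[panel_characteristics()]
  xd <- if (inherits(data_panel, "diagnostics_panel"))
    panel_values(data_panel) else unlist(data_panel)[panel_characteristics()]
  bad <- panel_characteristics()[is.na(xm) | is.na(xd)]
  if (length(bad) > 0)
    stop("undefined characteristics: ", paste(bad, collapse = ", "),
         call. = FALSE)
  zero <- panel_characteristics()[xd == 0]
  if (length(zero) > 0)
    stop("relative difference undefined (data value 0): ",
         paste(zero, collapse = ", "), call. = FALSE)
  sum(abs(xm - xd) / abs(xd))
}

#' Normalized per-diagnostic difference profiles
#'
#' For each model and each of the nine characteristics, the absolute
#' relative difference to the data is divided by the maximum of that
#' difference across models, so the model that fits the data the least on
#' a diagnostic scores exactly 1 there. Columns in which every model
#' matches the data exactly are returned as zeros with a message.
#'
#' @param panels Named list (length >= 2) of model `diagnostics_panel`s.
#' @param data_panel The reference `diagnostics_panel`.
#' @return A models x characteristics numeric matrix with values in
#'   \eqn{[0, 1]}, with attribute `raw` holding the unnormalized relative
#'   differences.
#' @export
normalized_profile <- function(panels, data_panel) {
  if (length(panels) < 2) stop("need at least 2 models", call. = FALSE)
  xd <- panel_values(data_panel)
  raw <- t(vapply(panels, function(p) {
    xm <- panel_values(p)
    abs(xm - xd) / abs(xd)
  }, numeric(length(panel_characteristics()))))
  colnames(raw) <- panel_characteristics()
  norm <- raw
  for (ch in colnames(raw)) {
    mx <- max(raw[, ch])
    if (mx == 0) {
      message(sprintf("all models match the data on %s; column left zero",
                      ch))
    } else {
      norm[, ch] <- raw[, ch] / mx
    }
  }
  attr(norm, "raw") <- raw
  norm
}

## Model registry ---------------------------------------------------------

#' Generate a model network by name
#'
#' Dispatch table over the 13 model codes. Non-embedded models (`er`,
#' `cf`, `rl`, `gd`, `ms`, `fh`, `ba`, `af`) take `n` and `m`; embedded
#' models (`rg`, `mw`, `dd`, `ddg`, `hdg`) take `coords` and `m` (`rg`
#' generates its own coordinates). Remaining model parameters are passed
#' via `params`; `cf` requires a reference graph `params$graph` to rewire.
#'
#' @param model Model code, lower case.
#' @param n,m Node and edge counts.
#' @param coords Coordinate matrix for embedded models.
#' @param params Named list of model-specific parameters.
#' @return An igraph object (for `rg`, the coordinates used are attached
#'   as attribute `coords`).
#' @export
generate_model <- function(model, n = NULL, m, coords = NULL,
                           params = list()) {
  model <- tolower(model)
  kern <- params$kernel
  g <- switch(model,
    er = gen_er(n, m),
    cf = {
      if (is.null(params$graph))
        stop("cf requires params$graph (reference graph to rewire)",
             call. = FALSE)
      do.call(gen_cf, c(list(g = params$graph),
                        params[intersect(names(params), "n_swaps")]))
    },
    rl = gen_rl(n, m),
    gd = gen_gd(n, m, kappa = params$kappa %||% (n / 20)),
    ms = gen_ms(n, m, module_size = params$module_size %||% 4),
    fh = gen_fh(n, m),
    ba = gen_ba(n, m, gamma = params$gamma %||% 1),
    af = gen_af(n, m, m0 = params$m0 %||% (m %/% 10),
                gamma = params$gamma %||% 1,
                delta = params$delta %||% 0.4,
                epsilon = params$epsilon %||% 2),
    rg = {
      out <- gen_rg(n, m)
      attr(out$graph, "coords") <- out$coords
      out$graph
    },
    mw = gen_mw(coords, m),
    dd = gen_dd(coords, m, kern),
    ddg = gen_ddg(coords, m, m0 = params$m0 %||% max(1, m %/% 100),
                  kernel = kern),
    hdg = gen_hdg(coords, m, m0 = params$m0 %||% (m %/% 2),
                  kernel = kern),
    stop(sprintf("unknown model '%s'", model), call. = FALSE))
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit model parameters to a target diagnostics panel
#'
#' Minimizes the mean difference metric \eqn{\Delta} between generated
#' model networks and a target panel over the named free parameters,
#' using the Nelder-Mead simplex (derivative-free) method. Each objective
#' evaluation averages \eqn{\Delta} over `realizations` model draws using
#' common random numbers (the same seed sequence at every evaluation), so
#' the stochastic objective is smooth in the parameters. Box constraints
#' are enforced by clamping inside the objective; integer-valued
#' parameters (e.g. seed-edge counts) are rounded inside the objective.
#'
#' @param model Model code (see [generate_model()]).
#' @param fixed_args Named list of fixed generator arguments (`n`, `m`,
#'   `coords`, `params`, and optionally `panel_settings`, a list passed to
#'   [diagnostics_panel()]).
#' @param free_params Named list, one entry per free parameter:
#'   `list(init =, lower =, upper =, integer = FALSE)`. Parameters named
#'   `kernel_exponent` (and similar `kernel_*`) are routed into the
#'   distance kernel.
#' @param data_panel Target `diagnostics_panel`.
#' @param realizations Model draws per objective evaluation; default 5.
#' @param maxit Nelder-Mead iteration cap; default 50.
#' @param seed Base seed for the common random numbers; default 1.
#' @return An object of class `model_fit`: `best_params`, `delta_best`,
#'   `trace` (data frame of evaluated parameters and \eqn{\Delta}),
#'   `realizations`, and the `optim` convergence code.
#' @export
fit_model <- function(model, fixed_args, free_params, data_panel,
                      realizations = 5, maxit = 50, seed = 1) {
  if (realizations < 1) stop("`realizations` must be >= 1", call. = FALSE)
  pnames <- names(free_params)
  lower <- vapply(free_params, function(p) p$lower, numeric(1))
  upper <- vapply(free_params, function(p) p$upper, numeric(1))
  init <- vapply(free_params, function(p) p$init, numeric(1))
  is_int <- vapply(free_params, function(p) isTRUE(p$integer), logical(1))
  ps <- fixed_args$panel_settings %||% list(tilings = 8,
                                            community_runs = 10)
  trace_env <- new.env()
  trace_env$rows <- list()
  objective <- function(theta) {
    theta <- pmin(pmax(theta, lower), upper)
    theta[is_int] <- round(theta[is_int])
    params <- fixed_args$params %||% list()
    for (ii in seq_along(pnames)) {
      nm <- pnames[ii]
      if (startsWith(nm, "kernel_")) {
        kp <- sub("^kernel_", "", nm)
        params$kernel$params[[kp]] <- theta[ii]
      } else {
        params[[nm]] <- theta[ii]
      }
    }
    deltas <- numeric(realizations)
    for (rep in seq_len(realizations)) {
      set.seed(seed + rep)             # common random numbers
      gi <- generate_model(model, n = fixed_args$n, m = fixed_args$m,
                           coords = fixed_args$coords, params = params)
      pan <- suppressMessages(do.call(diagnostics_panel, c(list(g = gi), ps)))
      deltas[rep] <- panel_delta(pan, data_panel)
    }
    val <- mean(deltas)
    trace_env$rows[[length(trace_env$rows) + 1]] <-
      c(setNames(theta, pnames), delta = val)
    val
  }
  v0 <- objective(init)
  if (!is.finite(v0)) stop("objective non-finite at init", call. = FALSE)
  opt <- optim(init, objective, method = "Nelder-Mead",
               control = list(maxit = maxit))
  trace <- as.data.frame(do.call(rbind, trace_env$rows))
  best_row <- which.min(trace$delta)
  best <- as.list(trace[best_row, pnames, drop = FALSE])
  best[is_int] <- lapply(best[is_int], round)
  out <- list(best_params = best, delta_best = trace$delta[best_row],
              trace = trace, realizations = realizations,
              convergence = opt$convergence, model = model, seed = seed)
  class(out) <- "model_fit"
  out
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("Model fit (%s, Nelder-Mead, %d realizations/eval)\n",
              x$model, x$realizations))
  cat(sprintf("  best delta = %.4f at %s  (%d evaluations)\n",
              x$delta_best,
              paste(names(x$best_params),
                    signif(unlist(x$best_params), 4),
                    sep = " = ", collapse = ", "),
              nrow(x$trace)))
  invisible(x)
}

## Panel serialization ----------------------------------------------------

#' Read/write a diagnostics panel as JSON
#'
#' The schema stores each of the nine characteristics (with `null` for
#' flagged/undefined entries), the degree summary, flags, and provenance.
#' `read_panel()` returns a list usable wherever a `diagnostics_panel` is
#' accepted by [panel_delta()] and [normalized_profile()].
#'
#' @param panel A `diagnostics_panel`.
#' @param path File path.
#' @export
write_panel <- function(panel, path) {
  vals <- as.list(panel_values(panel))
  obj <- list(characteristics = vals,
              degree = panel$degree[c("mode_degree", "mode_count",
                                      "min_degree", "max_degree",
                                      "mean_degree", "density")],
              flags = as.list(panel$flags),
              provenance = panel$provenance[c("tilings", "community_runs",
                                              "resolution", "min_part",
                                              "component_fraction",
                                              "mean_communities")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- obj$characteristics
  out <- lapply(vals, function(v) if (is.null(v)) NA_real_ else v)
  out$degree <- obj$degree
  out$flags <- unlist(obj$flags)
  out$provenance <- obj$provenance
  class(out) <- "diagnostics_panel"
  out
}
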