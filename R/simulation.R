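# Time integration of one (L0, H0) scenario.
#
# Per step (backward Euler, dt halving on rejection):
#   1. solve the 14 transport equations semi-implicitly on the current mesh
#      (own-species linear terms implicit, cross-species couplings explicit),
#   2. close the state: density closure, pressure solve, Darcy velocity,
#   3. move the free boundary by V_n * dt and remesh (structured re-gridding
#      with per-column field interpolation),
#   4. record the plaque weight.

#' Run one plaque-growth scenario
#'
#' Integrates the full model from the fixture initial plaque for a given blood
#' lipid pair. Deterministic: there is no randomness in the solver.
#'
#' @param L0 blood LDL level (mg/dL).
#' @param H0 blood HDL level (mg/dL).
#' @param days time horizon (day).
#' @param config optional configuration: a named list understood by
#'   [run_config()] (parameter overrides, geometry, `h`, `dt`, output cadence).
#' @return A `scenario_result`: tibble-accessible weight series `weights`
#'   (time, W, W_rel), the final state, and an event log.
#' @examples
#' \donttest{
#' res <- run_scenario(190, 40, days = 20, config = list(h = 0.004))
#' res$weights
#' }
#' @export
run_scenario <- function(L0, H0, days = 300, config = NULL) {
  stopifnot(L0 >= 0, H0 >= 0, days > 0)
  cfg <- run_config(config)
  p <- cfg$parameters
  p$L0 <- mgdl_to_gcm3(L0)
  p$H0 <- mgdl_to_gcm3(H0)
  viol <- validate_parameters(p)
  if (length(viol) > 0) stop(paste(viol, collapse = "; "))

  st <- make_fixture(cfg$fixture, h = cfg$h, params = p)
  cache <- fem_cache(st$mesh)
  st <- close_state(st, p, cache)

  W0 <- plaque_weight(st)
  out_times <- seq(0, days, by = cfg$output_every)
  weights <- tibble::tibble(time = 0, W = W0, W_rel = 1)
  events <- character(0)
  t <- 0
  dt <- cfg$dt
  next_out <- 2L  # index into out_times
  halvings <- 0L

  while (t < days - 1e-9) {
    step_dt <- min(dt, days - t)
    trial <- tryCatch(
      .step_once(st, p, step_dt, cache, cfg),
      plaque_dt_reject = function(e) e,
      error = function(e) e
    )
    if (inherits(trial, "plaque_dt_reject") ||
        (inherits(trial, "error") &&
         grepl("overcrowding|collapse", conditionMessage(trial)))) {
      dt <- dt / 2
      halvings <- halvings + 1L
      events <- c(events, sprintf("t=%.2f dt halved to %.4g (%s)", t, dt,
                                  conditionMessage(trial)))
      if (dt < cfg$dt / 64) {
        events <- c(events, sprintf("t=%.2f aborted: dt underflow", t))
        break
      }
      next
    }
    if (inherits(trial, "error")) stop(trial)
    st <- trial$state
    cache <- trial$cache
    t <- t + step_dt
    st$time <- t
    if (dt < cfg$dt) dt <- min(cfg$dt, dt * 2)  # gentle recovery
    while (next_out <= length(out_times) && t >= out_times[next_out] - 1e-9) {
      W <- plaque_weight(st)
      weights <- rbind(weights,
                       tibble::tibble(time = out_times[next_out], W = W,
                                      W_rel = W / W0))
      next_out <- next_out + 1L
    }
  }

  structure(list(
    weights = weights, state = st, W0 = W0,
    L0 = L0, H0 = H0, days = days, config = cfg,
    events = events, n_halvings = halvings
  ), class = "scenario_result")
}

# one backward-Euler step on the current mesh; returns state + fresh cache
.step_once <- function(st, p, dt, cache, cfg) {
  mesh <- st$mesh
  rr <- reaction_rhs(st, p)
  bc <- boundary_coefficients(st, p)
  sp <- .species_table()
  u <- st$u_elem
  drift_S <- chemotaxis_drift(st, p)
  clipped <- 0
  newf <- st$fields
  for (i in seq_len(nrow(sp))) {
    nm <- sp$name[i]
    D <- p[[sp$D[i]]]
    robin <- NULL
    if (!is.null(bc[[nm]])) {
      rb <- bc[[nm]]
      robin <- list(list(tag = rb$tag, b = rb$perm / D, X0 = rb$X0))
    }
    u_elem <- NULL
    if (sp$cell[i]) {
      u_elem <- u
      if (nm == "S") u_elem <- u + drift_S
    }
    sys <- assemble_transport(mesh, D = D, dt = dt, prev = st$fields[[nm]],
                              source = rr$source[, nm], decay = rr$decay[, nm],
                              u_elem = u_elem, robin = robin, cache = cache)
    v <- solve_transport(sys)
    neg <- v < 0
    if (any(neg)) {
      clipped <- clipped + sum(-v[neg])
      v[neg] <- 0
    }
    newf[[nm]] <- v
  }
  st$fields <- newf
  st$clipped_mass <- st$clipped_mass + clipped
  st <- close_state(st, p, cache)
  motion <- normal_velocity(st, p)
  st <- advance_boundary(st, motion, dt, cap = cfg$motion_cap)
  cache <- fem_cache(st$mesh)
  st <- close_state(st, p, cache)
  list(state = st, cache = cache)
}

#' Scenario/run configuration
#'
#' Normalizes a configuration list: `parameters` (overrides, see
#' [load_parameters()]), `fixture` (`"small-plaque"`, `"flat-strip"` or
#' `"annulus"`), `h` (target edge length, cm), `dt` (day), `output_every`
#' (day), `motion_cap` (fraction of layer spacing). May also be a YAML file
#' path with these keys.
#'
#' @param config named list, YAML path, or `NULL` for defaults.
#' @return A normalized configuration list.
#' @export
run_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  defaults <- list(fixture = "small-plaque", h = 0.002, dt = 0.5,
                   output_every = 5, motion_cap = 0.2)
  unknown <- setdiff(names(config),
                     c(names(defaults), "parameters"))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config[setdiff(names(config), "parameters")])
  cfg$parameters <- load_parameters(config$parameters)
  cfg
}

#' Fixture meshes and initial states
#'
#' Deterministic initial conditions (a documented fixture convention): inside
#' the domain, cells start at small uniform densities (monocyte level `M0`,
#' T cells 1e-5, SMCs 1e-4, foam cells 3e-3 g/cm^3 -- the "small formed
#' plaque" is foam-cell rich), chemicals and radicals at zero, ECM taking up
#' the rest of the total density.
#'
#' @param name `"small-plaque"` (channel with bump), `"flat-strip"` (channel,
#'   no bump) or `"annulus"`.
#' @param h target edge length (cm).
#' @param params parameters (for `M0` and the closure).
#' @return An open `plaque_state` (call [close_state()] before stepping).
#' @export
make_fixture <- function(name = "small-plaque", h = 0.002,
                         params = default_parameters()) {
  mesh <- switch(name,
    "small-plaque" = build_channel_domain(0.1, 0.01, bump_amp = 0.005,
                                          bump_width = 0.015, h = h),
    "flat-strip" = build_channel_domain(0.1, 0.01, bump_amp = 0, h = h),
    "annulus" = build_annulus_domain(0.09, 0.1, h = h),
    stop("unknown fixture: ", name)
  )
  new_state(mesh, fields = list(M = params$M0, T = 1e-5, S = 1e-4, F = 3e-3))
}

#' @export
print.scenario_result <- function(x, ...) {
  wN <- x$weights$W_rel[nrow(x$weights)]
  cat("<scenario_result> L0 = ", x$L0, " mg/dL, H0 = ", x$H0,
      " mg/dL, ", x$days, " days\n  W(end)/W(0) = ", signif(wN, 4),
      ", ", length(x$events), " events\n", sep = "")
  invisible(x)
}

#' Tidy a scenario result (weight trajectory)
#' @param x a `scenario_result`.
#' @param ... unused.
#' @return Tibble `time`, `W`, `W_rel` plus the scenario labels.
#' @export
tidy.scenario_result <- function(x, ...) {
  dplyr::mutate(x$weights, L0 = x$L0, H0 = x$H0)
}

#' One-row summary of a scenario result
#' @param x a `scenario_result`.
#' @param ... unused.
#' @return Tibble with `L0`, `H0`, `days`, `W0`, `W_end`, `W_rel`,
#'   `n_halvings`.
#' @export
glance.scenario_result <- function(x, ...) {
  tibble::tibble(L0 = x$L0, H0 = x$H0, days = x$days, W0 = x$W0,
                 W_end = x$weights$W[nrow(x$weights)],
                 W_rel = x$weights$W_rel[nrow(x$weights)],
                 n_halvings = x$n_halvings)
}

#' Plot a scenario weight trajectory
#' @param object a `scenario_result`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.scenario_result <- function(object, ...) {
  ggplot2::ggplot(object$weights, ggplot2::aes(x = .data$time,
                                               y = .data$W_rel)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::labs(
      x = "time (days)", y = "W(t) / W(0)",
      title = sprintf("Plaque weight, L0 = %g mg/dL, H0 = %g mg/dL",
                      object$L0, object$H0)) +
    ggplot2::theme_minimal()
}
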