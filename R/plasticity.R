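# State propagation under piecewise-constant stimulation ---------------------
#
# Each synapse class (the set of KC->MBON synapses driven by one odor) carries
# four variables: fast eligibility levels d, n that respond immediately to
# DAN/KC coincidence, and slow expressed effects D, N that low-pass filter
# them. Within one stimulation segment all drives are constant, so the system
# is linear with constant coefficients and is propagated exactly.

#' Synapse state of one synapse class
#'
#' Holds the fast (eligibility) and slow (expressed) plasticity variables for
#' the dopamine and nitric-oxide pathways. All four live in `[0, 1]`; the
#' naive state is all-zero, which corresponds to a normalized synaptic weight
#' of 1 under every weight rule.
#'
#' Fields may be equal-length numeric vectors, in which case propagation is
#' carried out elementwise (used internally to sweep parameter grids).
#'
#' @param d_fast,n_fast fast eligibility levels, DA and NO pathway.
#' @param d_slow,n_slow slow expressed effects (often written D and N).
#' @return An object of class `synapse_state`.
#' @export
synapse_state <- function(d_fast = 0, n_fast = 0, d_slow = 0, n_slow = 0) {
  s <- list(d_fast = d_fast, n_fast = n_fast, d_slow = d_slow, n_slow = n_slow)
  lens <- lengths(s)
  if (any(lens != lens[1])) stop("state fields must have equal length", call. = FALSE)
  for (f in names(s)) {
    if (!is.numeric(s[[f]]) || anyNA(s[[f]])) {
      stop("state field '", f, "' must be numeric and non-missing", call. = FALSE)
    }
    if (any(s[[f]] < -1e-12) || any(s[[f]] > 1 + 1e-12)) {
      stop("state field '", f, "' outside [0, 1]", call. = FALSE)
    }
  }
  structure(s, class = "synapse_state")
}

#' @export
print.synapse_state <- function(x, ...) {
  cat(sprintf("synapse state: d = %s, n = %s, D = %s, N = %s\n",
              format(x$d_fast, digits = 4), format(x$n_fast, digits = 4),
              format(x$d_slow, digits = 4), format(x$n_slow, digits = 4)))
  invisible(x)
}

#' One piecewise-constant stimulation segment
#'
#' A segment fixes, for `duration_s` seconds, the DAN drive and which odors
#' are present. `dan = "on"` is optogenetic (or reinforcer-driven) DAN
#' activation: synapse classes whose odor is present are paired (driven
#' towards 1 at rate `a_*`), classes whose odor is absent experience the
#' unpaired rule (decay at `b_*`). `dan = "background"` is the low spontaneous
#' DAN activity assumed after training (decay at `b_*_bg` for every class).
#' `dan = "off"` freezes the fast variables; the slow variables always relax
#' towards the fast ones regardless of drive.
#'
#' @param duration_s segment length in seconds (finite, `>= 0`).
#' @param dan one of `"off"`, `"on"`, `"background"`.
#' @param kc logical: whether the KCs of a synapse class are active. Either a
#'   single flag (single-class use) or a named logical vector over odors,
#'   e.g. `c(A = TRUE, B = FALSE)` (schedules over several classes).
#' @return An object of class `mb_segment`.
#' @export
segment <- function(duration_s, dan = c("off", "on", "background"),
                    kc = FALSE) {
  dan <- match.arg(dan)
  if (!is.numeric(duration_s) || length(duration_s) != 1L ||
      !is.finite(duration_s) || duration_s < 0) {
    stop("segment duration must be a finite non-negative number", call. = FALSE)
  }
  if (!is.logical(kc) || anyNA(kc)) stop("kc must be logical", call. = FALSE)
  structure(list(duration_s = duration_s, dan = dan, kc = kc),
            class = "mb_segment")
}

# whether a synapse class responding to `odors` is active in a segment
.class_active <- function(kc, odors) {
  if (is.null(names(kc))) return(any(kc))
  any(kc[intersect(names(kc), odors)])
}

# per-pathway relaxation rate (s^-1) and fixed point for one drive condition;
# rates are stored in min^-1 and converted here, at the propagation boundary
.seg_rates <- function(params, dan, active) {
  if (dan == "on") {
    if (active) {
      list(rho_d = params$a_d / 60, xi_d = 1, rho_n = params$a_n / 60, xi_n = 1)
    } else {
      list(rho_d = params$b_d / 60, xi_d = 0, rho_n = params$b_n / 60, xi_n = 0)
    }
  } else if (dan == "background") {
    list(rho_d = params$b_d_bg / 60, xi_d = 0,
         rho_n = params$b_n_bg / 60, xi_n = 0)
  } else if (dan == "off") {
    list(rho_d = 0, xi_d = NA_real_, rho_n = 0, xi_n = NA_real_)
  } else {
    stop("unknown dan drive: ", dan, call. = FALSE)
  }
}

#' Relaxation rate and fixed point implied by a segment
#'
#' Maps a segment's drive condition to, for each pathway, the exponential
#' relaxation rate `rho` (in s^-1, converted from the stored min^-1 rates)
#' and the fixed point the fast variable relaxes towards: 1 under pairing,
#' 0 under the unpaired or background rule. When the DAN is off no update
#' rule applies: `rho = 0` and the fixed point is reported as `NA` (the
#' current value is preserved).
#'
#' @param params a [plasticity_params()] object.
#' @param seg a [segment()].
#' @param kc_active logical; overrides the segment's `kc` field (required if
#'   that field is a multi-class named vector).
#' @return A data.frame with columns `pathway` ("DA", "NO"), `rho` and
#'   `x_inf`.
#' @export
segment_rates <- function(params, seg, kc_active = NULL) {
  stopifnot(inherits(seg, "mb_segment"))
  .check_params(params)
  if (is.null(kc_active)) {
    if (length(seg$kc) != 1L) {
      stop("segment has per-odor kc flags; supply kc_active for one class",
           call. = FALSE)
    }
    kc_active <- seg$kc
  }
  r <- .seg_rates(params, seg$dan, kc_active)
  data.frame(pathway = c("DA", "NO"),
             rho = c(r$rho_d[1], r$rho_n[1]),
             x_inf = c(r$xi_d[1], r$xi_n[1]))
}

# Exact solution over time t of
#   x' = rho * (xinf - x),   tau * y' = x - y
# for constant rho, xinf. With delta = x0 - xinf:
#   x(t) = xinf + delta e^{-rho t}
#   y(t) = xinf + delta/(1 - rho tau) e^{-rho t} + C e^{-t/tau},
# C fixed by y(0). At the resonance rho*tau = 1 the middle term degenerates
# into a t e^{-t/tau} term; the branch switches on |1 - rho tau| < 1e-9 to
# avoid catastrophic cancellation. rho = 0 encodes a frozen fast variable.
.relax <- function(x0, y0, rho, xinf, tau, t) {
  n <- max(length(x0), length(y0), length(rho), length(xinf), length(tau))
  x0 <- rep_len(x0, n); y0 <- rep_len(y0, n)
  rho <- rep_len(rho, n); xinf <- rep_len(xinf, n); tau <- rep_len(tau, n)
  xinf <- ifelse(rho == 0, x0, xinf)
  delta <- x0 - xinf
  ert <- exp(-rho * t)
  etau <- exp(-t / tau)
  x <- xinf + delta * ert
  rt <- rho * tau
  deg <- abs(1 - rt) < 1e-9
  y <- numeric(n)
  if (any(!deg)) {
    i <- !deg
    k <- delta[i] / (1 - rt[i])
    y[i] <- xinf[i] + k * ert[i] + (y0[i] - xinf[i] - k) * etau[i]
  }
  if (any(deg)) {
    i <- deg
    y[i] <- xinf[i] + (delta[i] * t / tau[i] + y0[i] - xinf[i]) * etau[i]
  }
  list(x = x, y = y)
}

# advance one synapse class (internal state list d, n, D, N of equal-length
# vectors) through t seconds of a constant drive
.advance_class <- function(st, params, dan, active, t) {
  r <- .seg_rates(params, dan, active)
  fd <- .relax(st$d, st$D, r$rho_d, r$xi_d, params$tau_d_s, t)
  fn <- .relax(st$n, st$N, r$rho_n, r$xi_n, params$tau_n_s, t)
  list(d = fd$x, n = fn$x, D = fd$y, N = fn$y)
}

.state_internal <- function(s) {
  list(d = s$d_fast, n = s$n_fast, D = s$d_slow, N = s$n_slow)
}
.state_public <- function(st) {
  synapse_state(d_fast = st$d, n_fast = st$n, d_slow = st$D, n_slow = st$N)
}

#' Propagate a synapse state through one segment (exact solution)
#'
#' Advances the four state variables by the closed-form solution of the
#' linear relaxation dynamics: the fast variable relaxes exponentially
#' towards its fixed point, and the slow variable follows it through a
#' first-order filter (see [segment_rates()] for the rate table). The
#' degenerate case `rho * tau = 1` is handled by its analytic limit. Bounds
#' `[0, 1]` are preserved by the dynamics; no clipping is applied.
#'
#' @inheritParams segment_rates
#' @param state a [synapse_state()].
#' @param seg a [segment()].
#' @return The propagated `synapse_state`.
#' @examples
#' s <- propagate_segment(synapse_state(),
#'                        segment(60, "on", kc = TRUE),
#'                        plasticity_params())
#' s$d_fast  # 1 - exp(-4.3)
#' @export
propagate_segment <- function(state, seg, params, kc_active = NULL) {
  stopifnot(inherits(state, "synapse_state"), inherits(seg, "mb_segment"))
  .check_params(params)
  if (is.null(kc_active)) {
    if (length(seg$kc) != 1L) {
      stop("segment has per-odor kc flags; supply kc_active for one class",
           call. = FALSE)
    }
    kc_active <- seg$kc
  }
  if (seg$duration_s == 0) return(state)
  st <- .advance_class(.state_internal(state), params, seg$dan, kc_active,
                       seg$duration_s)
  if (anyNA(unlist(st)) || any(!is.finite(unlist(st)))) {
    stop("propagation produced non-finite state", call. = FALSE)
  }
  .state_public(st)
}

#' Propagate a synapse state by fixed-step RK4 integration
#'
#' Reference integrator for [propagate_segment()]: classical 4th-order
#' Runge-Kutta with a fixed step on the same piecewise-constant dynamics.
#' Converges to the exact propagator as `dt -> 0`; with `dt = 0.01` s the two
#' agree to well below 1e-6 per component over protocol-scale segments.
#'
#' @inheritParams propagate_segment
#' @param dt integration step in seconds, `0 < dt <= duration` (a final
#'   partial step covers any remainder).
#' @return The propagated `synapse_state`.
#' @export
propagate_numeric <- function(state, seg, params, dt = 0.01,
                              kc_active = NULL) {
  stopifnot(inherits(state, "synapse_state"), inherits(seg, "mb_segment"))
  .check_params(params)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("dt must be a positive number", call. = FALSE)
  }
  if (is.null(kc_active)) {
    if (length(seg$kc) != 1L) {
      stop("segment has per-odor kc flags; supply kc_active for one class",
           call. = FALSE)
    }
    kc_active <- seg$kc
  }
  dur <- seg$duration_s
  if (dur == 0) return(state)
  if (dt > dur) stop("dt must not exceed the segment duration", call. = FALSE)
  r <- .seg_rates(params, seg$dan, kc_active)
  xi_d <- ifelse(r$rho_d == 0, 0, r$xi_d)
  xi_n <- ifelse(r$rho_n == 0, 0, r$xi_n)
  td <- params$tau_d_s
  tn <- params$tau_n_s
  st <- .state_internal(state)
  deriv <- function(s) {
    list(d = r$rho_d * (xi_d - s$d), n = r$rho_n * (xi_n - s$n),
         D = (s$d - s$D) / td, N = (s$n - s$N) / tn)
  }
  step <- function(s, h) {
    k1 <- deriv(s)
    k2 <- deriv(list(d = s$d + h / 2 * k1$d, n = s$n + h / 2 * k1$n,
                     D = s$D + h / 2 * k1$D, N = s$N + h / 2 * k1$N))
    k3 <- deriv(list(d = s$d + h / 2 * k2$d, n = s$n + h / 2 * k2$n,
                     D = s$D + h / 2 * k2$D, N = s$N + h / 2 * k2$N))
    k4 <- deriv(list(d = s$d + h * k3$d, n = s$n + h * k3$n,
                     D = s$D + h * k3$D, N = s$N + h * k3$N))
    list(d = s$d + h / 6 * (k1$d + 2 * k2$d + 2 * k3$d + k4$d),
         n = s$n + h / 6 * (k1$n + 2 * k2$n + 2 * k3$n + k4$n),
         D = s$D + h / 6 * (k1$D + 2 * k2$D + 2 * k3$D + k4$D),
         N = s$N + h / 6 * (k1$N + 2 * k2$N + 2 * k3$N + k4$N))
  }
  n_full <- floor(dur / dt + 1e-9)
  for (i in seq_len(n_full)) st <- step(st, dt)
  rem <- dur - n_full * dt
  if (rem > 1e-12) st <- step(st, rem)
  .state_public(st)
}

# States of every synapse class at the requested times.
#
# segments: list of mb_segment (contiguous in time, starting at 0)
# params:   plasticity_params, fields possibly vectors of common length m
# times:    sorted non-negative seconds, all within the schedule span
# class_map: named list, class label -> character vector of odors it responds
#            to (e.g. list(A = "A", B = "B"))
# initial:  optional named list of internal state lists per class
#
# Returns list per class of list(d, n, D, N), each an m x length(times)
# matrix.
.states_at_times <- function(segments, params, times, class_map,
                             initial = NULL) {
  m <- .param_len(params)
  classes <- names(class_map)
  nt <- length(times)
  if (nt && is.unsorted(times, strictly = FALSE)) {
    stop("sample times must be non-decreasing", call. = FALSE)
  }
  if (nt && any(times < -1e-9)) stop("sample times must be >= 0", call. = FALSE)
  st <- lapply(classes, function(cl) {
    if (!is.null(initial) && !is.null(initial[[cl]])) {
      lapply(initial[[cl]], rep_len, m)
    } else {
      list(d = rep(0, m), n = rep(0, m), D = rep(0, m), N = rep(0, m))
    }
  })
  names(st) <- classes
  out <- lapply(classes, function(cl) {
    list(d = matrix(NA_real_, m, nt), n = matrix(NA_real_, m, nt),
         D = matrix(NA_real_, m, nt), N = matrix(NA_real_, m, nt))
  })
  names(out) <- classes
  record <- function(i, states) {
    for (cl in classes) {
      out[[cl]]$d[, i] <<- states[[cl]]$d
      out[[cl]]$n[, i] <<- states[[cl]]$n
      out[[cl]]$D[, i] <<- states[[cl]]$D
      out[[cl]]$N[, i] <<- states[[cl]]$N
    }
  }
  t0 <- 0
  ti <- 1L
  while (ti <= nt && times[ti] <= 1e-9) {
    record(ti, st)
    ti <- ti + 1L
  }
  for (seg in segments) {
    t1 <- t0 + seg$duration_s
    acts <- vapply(classes, function(cl) .class_active(seg$kc, class_map[[cl]]),
                   logical(1))
    while (ti <= nt && times[ti] <= t1 + 1e-9) {
      dt <- min(max(times[ti] - t0, 0), seg$duration_s)
      snap <- st
      for (cl in classes) {
        snap[[cl]] <- .advance_class(st[[cl]], params, seg$dan, acts[[cl]], dt)
      }
      record(ti, snap)
      ti <- ti + 1L
    }
    if (seg$duration_s > 0) {
      for (cl in classes) {
        st[[cl]] <- .advance_class(st[[cl]], params, seg$dan, acts[[cl]],
                                   seg$duration_s)
      }
    }
    t0 <- t1
  }
  if (ti <= nt) {
    stop("sample time ", times[ti], " s lies beyond the schedule end (",
         t0, " s)", call. = FALSE)
  }
  attr(out, "final") <- st
  attr(out, "span") <- t0
  out
}

#' Run a stimulation schedule and return the state trajectory
#'
#' Propagates every synapse class through an ordered list of segments and
#' reports the state at each segment boundary plus any requested sample
#' times, as a tidy data.frame (one row per time per class).
#'
#' @param segments list of [segment()]s, contiguous in time starting at 0.
#' @param params a [plasticity_params()] object (scalar fields).
#' @param initial optional named list of [synapse_state()]s per class;
#'   defaults to the all-zero (naive) state.
#' @param sample_times optional increasing vector of extra times (seconds)
#'   within the schedule span.
#' @param classes named list mapping class labels to the odors they respond
#'   to; defaults to the odor names found in the segments (or a single
#'   anonymous class for unnamed `kc` flags).
#' @return A data.frame with columns `time_s`, `synapse_class`, `d_fast`,
#'   `n_fast`, `d_slow`, `n_slow`, of class `c("mb_trajectory",
#'   "data.frame")`.
#' @export
run_schedule <- function(segments, params, initial = NULL,
                         sample_times = NULL, classes = NULL) {
  if (length(segments) && !all(vapply(segments, inherits, TRUE, "mb_segment"))) {
    stop("segments must be a list of segment() objects", call. = FALSE)
  }
  .check_params(params)
  if (is.null(classes)) {
    odors <- unique(unlist(lapply(segments, function(s) names(s$kc))))
    classes <- if (length(odors)) {
      stats::setNames(as.list(odors), odors)
    } else {
      list(syn = character(0))
    }
  }
  if (!is.null(sample_times) && is.unsorted(sample_times, strictly = TRUE)) {
    stop("sample_times must be strictly increasing", call. = FALSE)
  }
  bounds <- cumsum(c(0, vapply(segments, `[[`, numeric(1), "duration_s")))
  times <- sort(unique(c(bounds, sample_times)))
  init <- NULL
  if (!is.null(initial)) {
    init <- lapply(initial, .state_internal)
  }
  stt <- .states_at_times(segments, params, times, classes, initial = init)
  rows <- do.call(rbind, lapply(names(classes), function(cl) {
    data.frame(time_s = times, synapse_class = cl,
               d_fast = stt[[cl]]$d[1, ], n_fast = stt[[cl]]$n[1, ],
               d_slow = stt[[cl]]$D[1, ], n_slow = stt[[cl]]$N[1, ])
  }))
  rows <- rows[order(rows$time_s, rows$synapse_class), ]
  rownames(rows) <- NULL
  class(rows) <- c("mb_trajectory", "data.frame")
  rows
}

#' @export
plot.mb_trajectory <- function(x, vars = c("d_slow", "n_slow"), ...) {
  cls <- unique(x$synapse_class)
  cols <- grDevices::hcl.colors(max(2L, length(cls) * length(vars)), "Dark 3")
  graphics::plot(range(x$time_s), c(0, 1), type = "n",
                 xlab = "time (s)", ylab = "plasticity variable", ...)
  i <- 1L
  for (cl in cls) {
    sub <- x[x$synapse_class == cl, ]
    for (v in vars) {
      graphics::lines(sub$time_s, sub[[v]], col = cols[i], lwd = 2)
      i <- i + 1L
    }
  }
  graphics::legend("topright",
                   legend = as.vector(outer(vars, cls, function(v, c) paste(c, v))),
                   col = cols[seq_len(length(cls) * length(vars))], lwd = 2,
                   bty = "n")
  invisible(x)
}
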