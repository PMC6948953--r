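# Training and test schedules ------------------------------------------------
#
# A protocol is an ordered list of segments over the two odor-driven synapse
# classes plus the times at which the performance index is read out. Odor A
# occupies the trained (CS+) slot of the initial conditioning; reported PIs
# are always in the odor-A frame, so reversal training shows up as a sign
# flip rather than a frame change.

.seg_off <- function(dur) segment(dur, "off", kc = c(A = FALSE, B = FALSE))
.seg_odor <- function(dur, odor, dan = "off") {
  segment(dur, dan, kc = c(A = odor == "A", B = odor == "B"))
}
.seg_dan_only <- function(dur) segment(dur, "on", kc = c(A = FALSE, B = FALSE))
.seg_background <- function(dur) {
  segment(dur, "background", kc = c(A = FALSE, B = FALSE))
}

# one conditioning bout: CS+ odor paired with DAN activation, a pause, then
# the control odor alone. During the pairing slot the CS- class experiences
# the unpaired rule (DAN on, its KCs silent); during the CS- slot the DAN is
# off, so naive CS- synapses are untouched.
.training_cycle <- function(cs_plus, pairing_s, gap_s, cs_minus_s) {
  cs_minus <- setdiff(c("A", "B"), cs_plus)
  segs <- list(.seg_odor(pairing_s, cs_plus, dan = "on"))
  if (gap_s > 0) segs <- c(segs, list(.seg_off(gap_s)))
  if (cs_minus_s > 0) segs <- c(segs, list(.seg_odor(cs_minus_s, cs_minus)))
  segs
}

#' Construct a protocol object
#'
#' @param name protocol label, used to match behavioral records to
#'   simulations.
#' @param segments ordered list of [segment()]s with per-odor `kc` flags over
#'   exactly the odors `A` and `B`.
#' @param cs_plus the odor in the trained slot of the reporting frame.
#' @param test_times strictly increasing times (seconds) at which PI is read.
#' @return An object of class `mb_protocol`.
#' @export
protocol <- function(name, segments, cs_plus = "A", test_times) {
  if (!length(segments) ||
      !all(vapply(segments, inherits, TRUE, "mb_segment"))) {
    stop("segments must be a non-empty list of segment() objects",
         call. = FALSE)
  }
  odors <- unique(unlist(lapply(segments, function(s) names(s$kc))))
  if (!setequal(odors, c("A", "B"))) {
    stop("protocol segments must flag exactly the odor classes A and B",
         call. = FALSE)
  }
  if (!cs_plus %in% c("A", "B")) stop("cs_plus must be 'A' or 'B'", call. = FALSE)
  if (!is.numeric(test_times) || !length(test_times) ||
      is.unsorted(test_times, strictly = TRUE)) {
    stop("test_times must be strictly increasing", call. = FALSE)
  }
  span <- sum(vapply(segments, `[[`, numeric(1), "duration_s"))
  if (any(test_times < 0) || any(test_times > span + 1e-9)) {
    stop("test_times must lie within the schedule span (0..", span, " s)",
         call. = FALSE)
  }
  structure(list(name = name, segments = segments, cs_plus = cs_plus,
                 test_times = test_times),
            class = "mb_protocol")
}

#' @export
print.mb_protocol <- function(x, ...) {
  cat(sprintf("protocol '%s': %d segments, %.0f s total, tests at %s s\n",
              x$name, length(x$segments), protocol_span(x),
              paste(x$test_times, collapse = ", ")))
  invisible(x)
}

#' Total scheduled duration of a protocol, in seconds
#' @param p an `mb_protocol`.
#' @export
protocol_span <- function(p) {
  sum(vapply(p$segments, `[[`, numeric(1), "duration_s"))
}

#' Odor-conditioning acquisition protocol
#'
#' `n_cycles` repetitions of a conditioning bout: `pairing_s` seconds of the
#' CS+ odor paired with DAN activation, `gap_s` seconds with nothing, then
#' `cs_minus_s` seconds of the control odor alone. PI is read immediately
#' after the last bout. The standard acquisition suite used throughout is
#' one 10 s bout, and one, three and ten 1 min bouts.
#'
#' @param n_cycles number of bouts, `>= 1`.
#' @param pairing_s,gap_s,cs_minus_s slot durations in seconds.
#' @param iti_s extra inter-trial interval inserted between bouts (the
#'   repeated bouts run back-to-back by default).
#' @param cs_plus the paired odor.
#' @param name optional label; defaults to e.g. `"acq_3x60s"`.
#' @return An `mb_protocol`.
#' @export
acquisition_protocol <- function(n_cycles = 1, pairing_s = 60, gap_s = 60,
                                 cs_minus_s = 60, iti_s = 0, cs_plus = "A",
                                 name = NULL) {
  if (!is.numeric(n_cycles) || n_cycles < 1) {
    stop("n_cycles must be >= 1", call. = FALSE)
  }
  n_cycles <- as.integer(n_cycles)
  if (min(pairing_s, gap_s, cs_minus_s, iti_s) < 0) {
    stop("durations must be >= 0", call. = FALSE)
  }
  segs <- list()
  for (k in seq_len(n_cycles)) {
    segs <- c(segs, .training_cycle(cs_plus, pairing_s, gap_s, cs_minus_s))
    if (iti_s > 0 && k < n_cycles) segs <- c(segs, list(.seg_off(iti_s)))
  }
  span <- sum(vapply(segs, `[[`, numeric(1), "duration_s"))
  name <- name %||% sprintf("acq_%dx%gs", n_cycles, pairing_s)
  protocol(name, segs, cs_plus = "A", test_times = span)
}

#' The standard acquisition suite
#'
#' @return Named list of the four standard protocols: `acq_1x10s`,
#'   `acq_1x1min`, `acq_3x1min`, `acq_10x1min`.
#' @export
standard_acquisition_suite <- function() {
  list(acq_1x10s = acquisition_protocol(1, pairing_s = 10, name = "acq_1x10s"),
       acq_1x1min = acquisition_protocol(1, name = "acq_1x1min"),
       acq_3x1min = acquisition_protocol(3, name = "acq_3x1min"),
       acq_10x1min = acquisition_protocol(10, name = "acq_10x1min"))
}

#' Retention protocol: training followed by background DAN activity
#'
#' Appends to a base protocol a quiet period during which the DANs fire at
#' their spontaneous background level (no odors present), eroding both
#' pathways' traces at the `b_*_bg` rates, and schedules PI reads at the
#' requested delays after the end of training.
#'
#' @param base an `mb_protocol` (typically an acquisition protocol).
#' @param delays_s strictly increasing delays (seconds, `>= 0`) after the end
#'   of the base schedule.
#' @param name optional label.
#' @return An `mb_protocol`.
#' @export
retention_protocol <- function(base, delays_s, name = NULL) {
  stopifnot(inherits(base, "mb_protocol"))
  if (!is.numeric(delays_s) || !length(delays_s) || any(delays_s < 0) ||
      is.unsorted(delays_s, strictly = TRUE)) {
    stop("delays_s must be strictly increasing and >= 0", call. = FALSE)
  }
  base_end <- protocol_span(base)
  gaps <- diff(c(0, delays_s))
  segs <- base$segments
  for (gp in gaps[gaps > 0]) segs <- c(segs, list(.seg_background(gp)))
  protocol(name %||% paste0(base$name, "_ret"), segs, cs_plus = base$cs_plus,
           test_times = base_end + delays_s)
}

#' Reversal-learning protocol
#'
#' `initial_cycles` standard bouts pairing odor A, then `reversal_cycles`
#' bouts in which the former control odor B is paired and odor A is presented
#' alone in the control slot. During each reversal pairing the odor-A
#' synapses experience the unpaired rule (DAN active, their KCs silent) and
#' decay at the `b_*` rates. PI is read (in the odor-A frame) after the
#' initial block and after each reversal bout.
#'
#' @param initial_cycles,reversal_cycles bout counts; `initial_cycles >= 1`,
#'   `reversal_cycles >= 0`.
#' @inheritParams acquisition_protocol
#' @return An `mb_protocol`.
#' @export
reversal_protocol <- function(initial_cycles = 3, reversal_cycles = 3,
                              pairing_s = 60, gap_s = 60, cs_minus_s = 60,
                              name = NULL) {
  if (initial_cycles < 1 || reversal_cycles < 0) {
    stop("initial_cycles must be >= 1 and reversal_cycles >= 0", call. = FALSE)
  }
  segs <- list()
  for (k in seq_len(initial_cycles)) {
    segs <- c(segs, .training_cycle("A", pairing_s, gap_s, cs_minus_s))
  }
  cycle_s <- pairing_s + gap_s + cs_minus_s
  tests <- initial_cycles * cycle_s
  for (k in seq_len(reversal_cycles)) {
    segs <- c(segs, .training_cycle("B", pairing_s, gap_s, cs_minus_s))
    tests <- c(tests, (initial_cycles + k) * cycle_s)
  }
  protocol(name %||% sprintf("reversal_%dplus%d", initial_cycles,
                             as.integer(reversal_cycles)),
           segs, cs_plus = "A", test_times = tests)
}

#' DAN-activation-without-odor protocol
#'
#' After a pretraining protocol, the DAN is activated repeatedly with no odor
#' present, so both synapse classes experience the unpaired rule and decay at
#' the `b_*` rates. PI is read after pretraining and after each activation.
#'
#' @param pretraining an `mb_protocol`.
#' @param n_activations number of DAN activations, `>= 0`.
#' @param activation_s duration of each activation (seconds); defaults to the
#'   60 s pairing slot of a training bout.
#' @param iti_s quiet interval between consecutive activations.
#' @param name optional label.
#' @return An `mb_protocol`.
#' @export
dan_only_protocol <- function(pretraining = acquisition_protocol(3),
                              n_activations = 5, activation_s = 60,
                              iti_s = 60, name = NULL) {
  stopifnot(inherits(pretraining, "mb_protocol"))
  if (n_activations < 0) stop("n_activations must be >= 0", call. = FALSE)
  n_activations <- as.integer(n_activations)
  segs <- pretraining$segments
  t <- protocol_span(pretraining)
  tests <- t
  for (k in seq_len(n_activations)) {
    if (k > 1 && iti_s > 0) {
      segs <- c(segs, list(.seg_off(iti_s)))
      t <- t + iti_s
    }
    segs <- c(segs, list(.seg_dan_only(activation_s)))
    t <- t + activation_s
    tests <- c(tests, t)
  }
  protocol(name %||% sprintf("dan_only_%dx", n_activations), segs,
           cs_plus = pretraining$cs_plus, test_times = tests)
}

#' Odor-exposure-without-DAN protocol
#'
#' After a pretraining protocol, both odors are presented repeatedly with the
#' DAN silent. No plasticity rule fires when the DAN is inactive, so the fast
#' variables are exactly unchanged and the trajectory is identical to a
#' blank schedule of the same length; the model predicts that odor exposure
#' alone cannot modify the memory.
#'
#' @param pretraining an `mb_protocol`.
#' @param n_exposures number of exposure rounds (each presents both odors).
#' @param exposure_s duration of each single-odor exposure.
#' @param gap_s quiet interval after each exposure.
#' @param name optional label.
#' @return An `mb_protocol`.
#' @export
odor_only_protocol <- function(pretraining = acquisition_protocol(3),
                               n_exposures = 3, exposure_s = 60, gap_s = 60,
                               name = NULL) {
  stopifnot(inherits(pretraining, "mb_protocol"))
  if (n_exposures < 0) stop("n_exposures must be >= 0", call. = FALSE)
  n_exposures <- as.integer(n_exposures)
  segs <- pretraining$segments
  t <- protocol_span(pretraining)
  tests <- t
  round_s <- 2 * (exposure_s + gap_s)
  for (k in seq_len(n_exposures)) {
    segs <- c(segs, list(.seg_odor(exposure_s, "A")))
    if (gap_s > 0) segs <- c(segs, list(.seg_off(gap_s)))
    segs <- c(segs, list(.seg_odor(exposure_s, "B")))
    if (gap_s > 0) segs <- c(segs, list(.seg_off(gap_s)))
    t <- t + round_s
    tests <- c(tests, t)
  }
  protocol(name %||% sprintf("odor_only_%dx", n_exposures), segs,
           cs_plus = pretraining$cs_plus, test_times = tests)
}

#' The named protocol library
#'
#' The protocols referenced by name in behavioral datasets: the standard
#' acquisition suite, a 24 h retention design after a single 1 min bout
#' (reads at 0, 3, 6 and 24 h), reversal training (3 + 3 bouts), five DAN
#' activations without odor after 3 x 1 min training, and three odor-only
#' exposure rounds after the same training.
#'
#' @return Named list of `mb_protocol` objects.
#' @export
protocol_library <- function() {
  suite <- standard_acquisition_suite()
  c(suite,
    list(
      decay_24h = retention_protocol(suite$acq_1x1min,
                                     delays_s = c(0, 3, 6, 24) * 3600,
                                     name = "decay_24h"),
      reversal_3plus3 = reversal_protocol(3, 3),
      dan_only_5x = dan_only_protocol(acquisition_protocol(3), 5),
      odor_only_3x = odor_only_protocol(acquisition_protocol(3), 3)
    ))
}

# rough classification used by the staged fit to route dataset rows
.protocol_kind <- function(p) {
  dans <- vapply(p$segments, `[[`, character(1), "dan")
  if (any(dans == "background")) return("retention")
  act <- vapply(p$segments, function(s) any(s$kc), logical(1))
  if (any(dans == "on" & !act)) return("dan_only")
  paired <- unique(unlist(lapply(p$segments[dans == "on"],
                                 function(s) names(s$kc)[s$kc])))
  if (length(paired) > 1) return("reversal")
  "acquisition"
}

#' Read or write a protocol as YAML
#'
#' Serializes the segment list, CS+ assignment and test times. A library of
#' the named protocols ships with the package
#' (`system.file("extdata", "protocols.yaml", package = "mbplast")`).
#'
#' @param p an `mb_protocol`.
#' @param path file path.
#' @export
write_protocol <- function(p, path) {
  stopifnot(inherits(p, "mb_protocol"))
  yaml::write_yaml(.protocol_to_list(p), path)
  invisible(path)
}

.protocol_to_list <- function(p) {
  list(name = p$name, cs_plus = p$cs_plus,
       test_times = as.numeric(p$test_times),
       segments = lapply(p$segments, function(s) {
         list(duration_s = s$duration_s, dan = s$dan,
              kc = as.list(s$kc))
       }))
}

.protocol_from_list <- function(x) {
  segs <- lapply(x$segments, function(s) {
    segment(s$duration_s, s$dan, kc = unlist(s$kc))
  })
  protocol(x$name, segs, cs_plus = x$cs_plus,
           test_times = as.numeric(x$test_times))
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop("protocol file not found: ", path, call. = FALSE)
  .protocol_from_list(yaml::read_yaml(path))
}

#' @rdname write_protocol
#' @param protocols named list of `mb_protocol`s
#'   (default: [protocol_library()]).
#' @export
write_protocol_library <- function(protocols = protocol_library(), path) {
  yaml::write_yaml(lapply(protocols, .protocol_to_list), path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol_library <- function(path) {
  if (!file.exists(path)) stop("protocol file not found: ", path, call. = FALSE)
  lapply(yaml::read_yaml(path), .protocol_from_list)
}
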