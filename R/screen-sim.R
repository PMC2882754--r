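# Two-colour antibody-uptake flow-cytometry screen simulator.
#
# Cells expressing a reporter construct internalize green-labelled antibody
# for a fixed uptake window; surface green is then quenched (never
# completely) and surface reporter is relabelled in red. Efficiently
# internalized constructs therefore show a high green-to-red ratio. The
# screen gates on that ratio inside a window of equal, relatively low
# surface expression, sorts a plus and a minus population, and recovers the
# inserts present in each.

#' Uptake model parameters
#'
#' Relative internalization rates follow the designer-construct efficiency
#' ladder measured for the reporter: canonical YXXphi and acidic dileucine
#' signals internalize at the reference rate 1; FXNPXY, the novel YXXXphiN
#' and 2-/5-spacer dileucine variants at about half that; a 4-spacer acidic
#' dileucine nearly as well as the canonical one (0.9); a bare dileucine is a
#' weak signal. A proline at -1 of the dileucine at least doubles efficiency
#' and a downstream DD pair about doubles it; modifiers multiply, capped at 1.
#'
#' @param baseline_rate relative rate for tails with no recognised signal.
#' @param weak_dileucine_rate relative rate for a bare LL/LI.
#' @param variant_rate relative rate for FXNPXY / YXXXphiN / atypical-spacer
#'   dileucines ("about half" the reference).
#' @param four_spacer_rate relative rate for the 4-spacer acidic dileucine
#'   ("nearly as efficiently").
#' @param proline_boost,dd_boost multiplicative modifiers for P at -1 of the
#'   dileucine and for a downstream DD pair.
#' @param quench_efficiency fraction of surface green signal removed by the
#'   quenching antibody; strictly below 1 ("quenching is never 100%").
#' @param uptake_duration uptake window in minutes.
#' @param rate_constant first-order uptake rate constant (per minute) of a
#'   construct with relative rate 1, before saturation damping.
#' @param expression_dispersion log-scale SD of the per-cell surface
#'   expression level.
#' @param measurement_noise log-scale SD of per-channel multiplicative noise.
#' @param saturation_scale expression level above which uptake is damped
#'   ("saturation of the machinery"); damping factor min(1, 2s/(s+E)).
#' @return object of class `uptake_model`.
#' @export
uptake_model <- function(baseline_rate = 0.05,
                         weak_dileucine_rate = 0.25,
                         variant_rate = 0.5,
                         four_spacer_rate = 0.9,
                         proline_boost = 2,
                         dd_boost = 2,
                         quench_efficiency = 0.9,
                         uptake_duration = 40,
                         rate_constant = 0.05,
                         expression_dispersion = 0.6,
                         measurement_noise = 0.2,
                         saturation_scale = 5) {
  stopifnot(baseline_rate > 0, quench_efficiency >= 0, quench_efficiency < 1,
            uptake_duration > 0, rate_constant > 0,
            expression_dispersion >= 0, measurement_noise >= 0,
            saturation_scale > 0)
  structure(list(baseline_rate = baseline_rate,
                 weak_dileucine_rate = weak_dileucine_rate,
                 variant_rate = variant_rate,
                 four_spacer_rate = four_spacer_rate,
                 proline_boost = proline_boost, dd_boost = dd_boost,
                 quench_efficiency = quench_efficiency,
                 uptake_duration = uptake_duration,
                 rate_constant = rate_constant,
                 expression_dispersion = expression_dispersion,
                 measurement_noise = measurement_noise,
                 saturation_scale = saturation_scale),
            class = "uptake_model")
}

# dileucine-like cores (LL or LI) with given number of x spacers after [DE]
spacer_dileucine <- function(k) {
  compile_pattern(paste(c("[DE]", rep("x", k), "L", "[LI]"), collapse = " "),
                  name = paste0("dileucine_", k, "spacer"))
}

#' Relative internalization rate of a tail under the uptake model
#'
#' Rules are applied in order; the first matching rule sets the base rate,
#' then the proline and downstream-DD modifiers are applied to
#' dileucine-driven rates and the result is capped at 1:
#' \enumerate{
#'   \item YXXphi or canonical acidic dileucine: 1.
#'   \item 4-spacer acidic dileucine: `four_spacer_rate`.
#'   \item FXNPXY, YXXXphiN, or a 2-/5-spacer acidic dileucine:
#'     `variant_rate`.
#'   \item bare LL/LI: `weak_dileucine_rate`.
#'   \item otherwise: `baseline_rate`.
#' }
#'
#' @param tail a [cytoplasmic_tail()] or tail sequence string.
#' @param model an [uptake_model()].
#' @return relative rate in (0, 1\].
#' @examples
#' internalization_rate("PEAAALLA")  # 1: canonical acidic dileucine
#' internalization_rate("PFANPAYA")  # 0.5
#' @export
internalization_rate <- function(tail, model = uptake_model()) {
  stopifnot(inherits(model, "uptake_model"))
  seq <- toupper(tail_sequence(tail))
  b <- builtin_motifs()
  dileucine_core <- compile_pattern("L [LI]", name = "LL")
  ll_hits <- scan_tail(seq, dileucine_core)
  rate <- NULL
  dileucine_driven <- FALSE
  if (has_motif(seq, b$YXXphi) || has_motif(seq, b$dileucine)) {
    rate <- 1
    dileucine_driven <- has_motif(seq, b$dileucine)
  } else if (has_motif(seq, spacer_dileucine(4L))) {
    rate <- model$four_spacer_rate
    dileucine_driven <- TRUE
  } else if (has_motif(seq, b$FXNPXY) || has_motif(seq, b$YXXXphiN)) {
    rate <- model$variant_rate
  } else if (has_motif(seq, spacer_dileucine(2L)) ||
             has_motif(seq, spacer_dileucine(5L))) {
    rate <- model$variant_rate
    dileucine_driven <- TRUE
  } else if (nrow(ll_hits) > 0L) {
    rate <- model$weak_dileucine_rate
    dileucine_driven <- TRUE
  } else {
    return(model$baseline_rate)
  }
  if (dileucine_driven && nrow(ll_hits) > 0L) {
    chars <- seq_chars(seq)
    for (i in seq_len(nrow(ll_hits))) {
      s <- ll_hits$start[i]; e <- ll_hits$end[i]
      boost <- 1
      if (s > 1L && chars[s - 1L] == "P") boost <- boost * model$proline_boost
      downstream <- substr(seq, e + 1L, min(nchar(seq), e + 10L))
      if (grepl("DD", downstream, fixed = TRUE)) {
        boost <- boost * model$dd_boost
      }
      rate <- max(rate, min(1, rate * boost))
    }
  }
  min(1, rate)
}

#' Simulate per-cell two-colour measurements
#'
#' Each cell expresses one construct (assigned round-robin so every construct
#' is represented, then shuffled). Per cell, the latent surface expression E
#' is log-normal; the internalized fraction over the uptake window is
#' `f = 1 - exp(-k * t)` with `k = rate_constant * relative_rate`, damped
#' multiplicatively by `min(1, 2s/(s+E))` above the saturation scale; then
#' `green = E * (f + (1 - quench) * (1 - f)) * noise` (internalized plus
#' unquenched surface signal) and `red = E * (1 - f) * noise` (surface
#' relabel).
#'
#' @param constructs named numeric vector of relative rates (names =
#'   construct ids), or a list of `tail_construct` objects (rates are then
#'   computed from their insert-bearing tail peptides).
#' @param model an [uptake_model()].
#' @param n_cells number of cells.
#' @param seed integer seed.
#' @return data frame with columns `construct_id`, `rate`, `expression`,
#'   `green`, `red`.
#' @export
simulate_cells <- function(constructs, model = uptake_model(), n_cells, seed) {
  stopifnot(inherits(model, "uptake_model"), n_cells >= 1L)
  rates <- construct_rates(constructs, model)
  if (length(rates) == 0L) stop("empty construct set")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  idx <- sample(rep_len(seq_along(rates), n_cells))
  E <- stats::rlnorm(n_cells, meanlog = 0, sdlog = model$expression_dispersion)
  damp <- pmin(1, 2 * model$saturation_scale / (model$saturation_scale + E))
  k <- model$rate_constant * rates[idx] * damp
  f <- 1 - exp(-k * model$uptake_duration)
  noise_g <- stats::rlnorm(n_cells, 0, model$measurement_noise)
  noise_r <- stats::rlnorm(n_cells, 0, model$measurement_noise)
  data.frame(construct_id = names(rates)[idx], rate = unname(rates[idx]),
             expression = E,
             green = E * (f + (1 - model$quench_efficiency) * (1 - f)) * noise_g,
             red = E * (1 - f) * noise_r,
             stringsAsFactors = FALSE)
}

construct_rates <- function(constructs, model) {
  if (is.numeric(constructs)) {
    rates <- constructs
    if (is.null(names(rates))) {
      names(rates) <- paste0("construct", seq_along(rates))
    }
    return(rates)
  }
  stopifnot(is.list(constructs))
  rates <- vapply(constructs, function(cc) {
    tail_seq <- if (inherits(cc, "tail_construct")) cc$tail_peptide
                else tail_sequence(cc)
    internalization_rate(tail_seq, model)
  }, 0)
  ids <- vapply(seq_along(constructs), function(i) {
    cc <- constructs[[i]]
    if (inherits(cc, "tail_construct")) cc$fragment_id
    else if (inherits(cc, "cytoplasmic_tail")) cc$protein_id
    else names(constructs)[i] %||% paste0("construct", i)
  }, "")
  names(rates) <- make.unique(ids)
  rates
}

#' Gate configuration
#'
#' Ratio gates are expressed as percentiles of the in-window green/red ratio
#' by default (`plus_gate` = lower percentile bound of the plus population,
#' `minus_gate` = upper percentile bound of the minus population), mirroring
#' sorting the extreme deciles; absolute ratio thresholds can be given
#' instead with `percentile = FALSE`. The expression window is an interval of
#' percentiles of the windowing channel (`"total"` = green + red, a proxy for
#' expression, or `"red"` = surface signal), selecting cells of equal and
#' relatively low surface expression.
#'
#' @param plus_gate plus-gate bound (percentile in \[0,1\], or ratio value).
#' @param minus_gate minus-gate bound (percentile in \[0,1\], or ratio value).
#' @param percentile interpret gates as percentiles?
#' @param expression_window two percentiles of the windowing channel.
#' @param window_channel `"total"` or `"red"`.
#' @return object of class `gate_config`.
#' @export
gate_config <- function(plus_gate = 0.9, minus_gate = 0.1, percentile = TRUE,
                        expression_window = c(0.05, 0.5),
                        window_channel = c("total", "red")) {
  window_channel <- match.arg(window_channel)
  stopifnot(length(expression_window) == 2L,
            expression_window[1] <= expression_window[2])
  if (percentile && plus_gate <= minus_gate) {
    stop("percentile gates must be disjoint: plus_gate > minus_gate required")
  }
  if (!percentile && plus_gate <= minus_gate) {
    stop("ratio gates must be disjoint: plus_gate > minus_gate required")
  }
  structure(list(plus_gate = plus_gate, minus_gate = minus_gate,
                 percentile = isTRUE(percentile),
                 expression_window = expression_window,
                 window_channel = window_channel),
            class = "gate_config")
}

#' Apply expression-window and ratio gates to cell measurements
#'
#' Cells outside the expression window are excluded from both populations;
#' the remaining cells are assigned to the plus population (ratio at or above
#' the plus bound), the minus population (ratio at or below the minus bound),
#' or left ungated. The populations are disjoint.
#'
#' @param measurements data frame from [simulate_cells()].
#' @param gates a [gate_config()].
#' @return list with data frames `plus`, `minus`, `ungated` (in-window cells
#'   in neither gate) and `excluded` (outside the window), plus the realized
#'   `ratio_bounds`.
#' @export
apply_gates <- function(measurements, gates = gate_config()) {
  stopifnot(inherits(gates, "gate_config"))
  if (nrow(measurements) == 0L) stop("empty measurement set")
  channel <- if (gates$window_channel == "total") {
    measurements$green + measurements$red
  } else {
    measurements$red
  }
  lim <- stats::quantile(channel, gates$expression_window, names = FALSE)
  in_window <- channel >= lim[1] & channel <= lim[2]
  mw <- measurements[in_window, , drop = FALSE]
  excluded <- measurements[!in_window, , drop = FALSE]
  ratio <- mw$green / pmax(mw$red, .Machine$double.eps)
  if (nrow(mw) == 0L) {
    bounds <- c(plus = NA_real_, minus = NA_real_)
    plus <- mw; minus <- mw; ungated <- mw
  } else {
    bounds <- if (gates$percentile) {
      c(plus = stats::quantile(ratio, gates$plus_gate, names = FALSE),
        minus = stats::quantile(ratio, gates$minus_gate, names = FALSE))
    } else {
      c(plus = gates$plus_gate, minus = gates$minus_gate)
    }
    in_plus <- ratio >= bounds["plus"]
    in_minus <- ratio <= bounds["minus"] & !in_plus
    plus <- mw[in_plus, , drop = FALSE]
    minus <- mw[in_minus, , drop = FALSE]
    ungated <- mw[!in_plus & !in_minus, , drop = FALSE]
  }
  list(plus = plus, minus = minus, ungated = ungated, excluded = excluded,
       ratio_bounds = bounds)
}

#' Run the full screen and score it against planted truth
#'
#' Simulates cells, gates them, tallies the construct ids recovered in each
#' gate (a construct is recovered when at least `min_cells` of its cells land
#' in the gate, abstracting the PCR recovery step), and scores the plus gate
#' against a truth labelling: precision = fraction of plus-gate recoveries
#' that are truly signal-bearing; recall = fraction of signal-bearing
#' constructs recovered in the plus gate.
#'
#' @param constructs as in [simulate_cells()].
#' @param truth named logical vector: is each construct signal-bearing?
#'   Names must cover every construct id.
#' @param model an [uptake_model()].
#' @param gates a [gate_config()].
#' @param n_cells number of cells to simulate.
#' @param seed integer seed.
#' @param min_cells minimum gate tally for a construct to count as recovered.
#' @return object of class `screen_result`: the gated populations, per-gate
#'   recovery tallies, recovered id vectors, `precision` and `recall`
#'   (precision is `NA` with a warning when the plus gate recovers nothing).
#' @export
simulate_screen <- function(constructs, truth, model = uptake_model(),
                            gates = gate_config(), n_cells, seed,
                            min_cells = 3L) {
  cells <- simulate_cells(constructs, model, n_cells, seed)
  gated <- apply_gates(cells, gates)
  tally <- function(pop) {
    if (nrow(pop) == 0L) return(integer(0))
    t <- table(pop$construct_id)
    stats::setNames(as.integer(t), names(t))
  }
  plus_tally <- tally(gated$plus)
  minus_tally <- tally(gated$minus)
  recovered_plus <- names(plus_tally)[plus_tally >= min_cells]
  recovered_minus <- names(minus_tally)[minus_tally >= min_cells]
  stopifnot(all(recovered_plus %in% names(truth)))
  signal_ids <- names(truth)[truth]
  if (length(recovered_plus) == 0L) {
    warning("empty plus-gate recovery: precision undefined")
    precision <- NA_real_
  } else {
    precision <- mean(recovered_plus %in% signal_ids)
  }
  recall <- if (length(signal_ids) == 0L) NA_real_ else {
    mean(signal_ids %in% recovered_plus)
  }
  structure(list(cells = cells, plus = gated$plus, minus = gated$minus,
                 ungated = gated$ungated, excluded = gated$excluded,
                 plus_tally = plus_tally, minus_tally = minus_tally,
                 recovered_plus = recovered_plus,
                 recovered_minus = recovered_minus,
                 precision = precision, recall = recall),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> plus ", nrow(x$plus), " cells / ",
      length(x$recovered_plus), " constructs; minus ", nrow(x$minus),
      " cells / ", length(x$recovered_minus), " constructs; precision ",
      signif(x$precision, 3), ", recall ", signif(x$recall, 3), "\n",
      sep = "")
  invisible(x)
}
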