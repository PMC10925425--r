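## HDX-MS peptide-level analysis: loading vendor-style cluster exports,
## back-exchange correction, state comparison, equilibration kinetics, and
## mapping uptake onto structure regions.

#' Load a peptide-level HDX table
#'
#' Reads a delimited text file (comma or tab, autodetected) with columns
#' `state, start, end, sequence, exposure_min, replicate, value`. Under the
#' `"uptake"` dialect, `value` is deuterium uptake in Da. Under the
#' `"centroid"` dialect, `value` is a centroid mass and uptake is obtained by
#' subtracting each peptide's mean undeuterated (0 min) centroid within its
#' state; every peptide/state must then carry a 0 min reference.
#'
#' @param path Input file path.
#' @param dialect `"uptake"` or `"centroid"`.
#' @return data.frame of peptide records with a computed `uptake` column (Da).
#' @export
load_peptide_table <- function(path, dialect = c("uptake", "centroid")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop2("file not found: ", path)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  tbl <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  needed <- c("state", "start", "end", "sequence", "exposure_min",
              "replicate", "value")
  miss <- setdiff(needed, names(tbl))
  if (length(miss)) stop2("missing columns: ", paste(miss, collapse = ", "))
  validate_peptide_records(tbl)
  if (dialect == "uptake") {
    tbl$uptake <- tbl$value
  } else {
    key <- paste(tbl$state, tbl$start, tbl$end, tbl$sequence, sep = "|")
    ref <- tapply(tbl$value[tbl$exposure_min == 0], key[tbl$exposure_min == 0],
                  mean)
    missing_ref <- setdiff(unique(key), names(ref))
    if (length(missing_ref))
      stop2("no 0 min (undeuterated) reference for: ",
            paste(missing_ref, collapse = "; "))
    tbl$uptake <- tbl$value - as.numeric(ref[key])
  }
  tbl
}

validate_peptide_records <- function(tbl) {
  if (any(tbl$end < tbl$start)) stop2("peptide with end < start")
  if (any(nchar(tbl$sequence) != tbl$end - tbl$start + 1))
    stop2("sequence length does not match start/end bounds")
  if (any(tbl$exposure_min < 0)) stop2("negative exposure time")
  invisible(tbl)
}

#' Exchangeable amide count of a peptide
#'
#' Backbone amides that report in HDX-MS: the N-terminal residue has no
#' amide deuterium to retain, the second residue back-exchanges too fast to
#' measure, and prolines have no amide hydrogen. The count is therefore
#' `length - 2 - (prolines at positions 2..length)`, floored at 0.
#'
#' @param sequence One-letter amino-acid string.
#' @return Integer count.
#' @export
count_exchangeable <- function(sequence) {
  res <- strsplit(toupper(sequence), "")[[1]]
  if (!all(res %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
    stop2("unknown amino-acid letter in sequence: ", sequence)
  length(exchangeable_positions(sequence))
}

## Relative positions (1-based within the peptide) whose amides report:
## positions 3..n excluding prolines, dropping one further position when
## residue 2 is a proline so the count matches the stated accounting rule.
exchangeable_positions <- function(sequence) {
  res <- strsplit(toupper(sequence), "")[[1]]
  n <- length(res)
  if (n < 3) return(integer(0))
  pos <- setdiff(3:n, which(res == "P"))
  if (n >= 2 && res[2] == "P" && length(pos) > 0) pos <- pos[-1]
  pos
}

#' Build per-peptide uptake curves from records
#'
#' Aggregates replicate uptake values into mean and SD per exposure time and
#' applies the global back-exchange correction.
#'
#' @param records Peptide records (one state), as from [load_peptide_table()].
#' @param be Global back-exchange fraction in `[0, 1)`; default 0.25.
#' @return List of `uptake_curve` objects, one per peptide, each a list with
#'   peptide identity, `times`, `mean_uptake`, `sd`, `corrected_uptake`,
#'   `corrected_sd`, `n_exchangeable`, `n_replicates` and a `soft_violation`
#'   flag raised when corrected uptake exceeds the exchangeable count by more
#'   than 3 SD.
#' @export
uptake_curves <- function(records, be = 0.25) {
  validate_peptide_records(records)
  key <- paste(records$state, records$start, records$end, records$sequence,
               sep = "|")
  lapply(unique(key), function(k) {
    r <- records[key == k, , drop = FALSE]
    times <- sort(unique(r$exposure_min))
    m <- vapply(times, function(t) mean(r$uptake[r$exposure_min == t]), 1)
    s <- vapply(times, function(t) stats::sd(r$uptake[r$exposure_min == t]), 1)
    nrep <- vapply(times, function(t) sum(r$exposure_min == t), 1L)
    curve <- structure(list(
      state = r$state[1], start = r$start[1], end = r$end[1],
      sequence = r$sequence[1], times = times, mean_uptake = m, sd = s,
      corrected_uptake = m, corrected_sd = s,
      n_exchangeable = count_exchangeable(r$sequence[1]),
      n_replicates = nrep, be = 0, soft_violation = FALSE
    ), class = "uptake_curve")
    correct_back_exchange(curve, be)
  })
}

#' Apply a global back-exchange correction to an uptake curve
#'
#' Measured uptake underestimates true labeling because a fraction `be` of
#' the deuterium is lost during workup; the correction divides measured means
#' (and SDs) by `1 - be`. Corrected uptake above the peptide's exchangeable
#' amide count by more than 3 SD raises a soft flag, never an error.
#'
#' @param curve An `uptake_curve`.
#' @param be Back-exchange fraction in `[0, 1)`.
#' @return The corrected `uptake_curve`.
#' @export
correct_back_exchange <- function(curve, be = 0.25) {
  if (!is.numeric(be) || be < 0 || be >= 1)
    stop2("back-exchange fraction must be in [0, 1)")
  curve$corrected_uptake <- curve$mean_uptake / (1 - be)
  curve$corrected_sd <- curve$sd / (1 - be)
  curve$be <- be
  sd0 <- ifelse(is.na(curve$corrected_sd), 0, curve$corrected_sd)
  curve$soft_violation <- any(curve$corrected_uptake >
                                curve$n_exchangeable + 3 * sd0)
  curve
}

safe_t_test <- function(a, b) {
  diff <- mean(a) - mean(b)
  if (stats::sd(c(a - mean(a), b - mean(b))) < 1e-12) {
    ## degenerate zero-variance replicates: identical means are certain
    return(if (abs(diff) < 1e-12) 1 else 0)
  }
  stats::t.test(a, b, var.equal = TRUE)$p.value
}

#' Compare deuterium uptake of one peptide across ligand states
#'
#' Per nonzero exposure time, a two-sided equal-variance two-sample t-test on
#' replicate uptake (two states), or a one-way ANOVA when more states are
#' supplied. The overall test is a one-way ANOVA across states pooling all
#' nonzero timepoints. The peptide is called significant when the overall
#' p-value is below `alpha` AND at least one per-time p-value is below
#' `alpha` (a deliberate conjunction; both raw outputs are returned so other
#' rules can be applied).
#'
#' @param records Peptide records for a single peptide covering >= 2 states
#'   with identical exposure grids and >= 2 replicates per point.
#' @param alpha Significance level (default 0.05).
#' @param be Back-exchange fraction used for the reported corrected
#'   differences (tests run on raw replicate uptake; the correction is a
#'   common scale factor and does not change p-values).
#' @return An `uptake_comparison`: list with peptide identity, `per_time`
#'   data.frame (time, difference of corrected means, p), `overall_p`,
#'   `alpha`, `significant`.
#' @export
compare_states <- function(records, alpha = 0.05, be = 0.25) {
  validate_peptide_records(records)
  states <- unique(records$state)
  if (length(states) < 2) stop2("need >= 2 states to compare")
  pid <- unique(paste(records$start, records$end, records$sequence))
  if (length(pid) > 1) stop2("records span more than one peptide")
  grids <- lapply(states, function(s)
    sort(unique(records$exposure_min[records$state == s])))
  if (!all(vapply(grids, identical, TRUE, grids[[1]])))
    stop2("exposure-time grids differ between states (no interpolation)")
  times <- grids[[1]][grids[[1]] > 0]
  if (length(times) == 0) stop2("no nonzero exposure times")
  per_time <- do.call(rbind, lapply(times, function(t) {
    vals <- lapply(states, function(s)
      records$uptake[records$state == s & records$exposure_min == t])
    if (any(vapply(vals, length, 1L) < 2))
      stop2("need >= 2 replicates per state and timepoint")
    p <- if (length(states) == 2) safe_t_test(vals[[1]], vals[[2]])
    else {
      df <- data.frame(v = unlist(vals),
                       s = rep(states, vapply(vals, length, 1L)))
      summary(stats::aov(v ~ s, data = df))[[1]][["Pr(>F)"]][1]
    }
    data.frame(time = t,
               diff_corrected = (mean(vals[[1]]) - mean(vals[[2]])) / (1 - be),
               p = p)
  }))
  nz <- records[records$exposure_min > 0, , drop = FALSE]
  overall_p <- if (stats::sd(nz$uptake) < 1e-12) 1 else
    summary(stats::aov(uptake ~ state, data = nz))[[1]][["Pr(>F)"]][1]
  structure(list(start = records$start[1], end = records$end[1],
                 sequence = records$sequence[1], states = states,
                 per_time = per_time, overall_p = overall_p, alpha = alpha,
                 significant = overall_p < alpha & any(per_time$p < alpha)),
            class = "uptake_comparison")
}

#' Time to deuterium-uptake equilibration of a peptide
#'
#' Fits `uptake(t) = plateau * (1 - exp(-rate * t))` by nonlinear least
#' squares and reports the time to reach 95% of plateau, `t95 = ln(20)/rate`.
#' The result is flagged unreliable (never an exception) when the fit fails,
#' the fitted plateau exceeds the last measured uptake by more than 25%
#' (plateau not approached within the window), or the rate standard error
#' exceeds the rate.
#'
#' @param curve An `uptake_curve` with >= 3 nonzero timepoints.
#' @param corrected Fit corrected (default) or raw mean uptake.
#' @return An `equilibration_result`: list with peptide identity, `plateau`
#'   (Da), `rate` (1/min), `rate_se`, `t95` (min), `reliable`, `reason`.
#' @export
equilibration_time <- function(curve, corrected = TRUE) {
  stopifnot(inherits(curve, "uptake_curve"))
  y <- if (corrected) curve$corrected_uptake else curve$mean_uptake
  t <- curve$times
  keep <- t > 0
  if (sum(keep) < 3) stop2("need >= 3 nonzero timepoints")
  t <- t[keep]; y <- y[keep]
  fail <- function(reason) structure(
    list(state = curve$state, start = curve$start, end = curve$end,
         plateau = NA_real_, rate = NA_real_, rate_se = NA_real_,
         t95 = NA_real_, reliable = FALSE, reason = reason),
    class = "equilibration_result")
  if (max(abs(y)) < 1e-9) return(fail("flat curve; no uptake to fit"))
  p0 <- max(y)
  r0 <- max(y[1] / (p0 * t[1]), 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ plateau * (1 - exp(-rate * t)),
                      start = list(plateau = p0, rate = r0),
                      lower = c(plateau = 0, rate = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("non-convergent fit"))
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(plateau = NA, rate = NA))
  reliable <- TRUE; reason <- ""
  if (est["plateau"] > 1.25 * max(y)) {
    reliable <- FALSE; reason <- "plateau not approached within measured window"
  } else if (is.finite(se["rate"]) && se["rate"] > est["rate"]) {
    reliable <- FALSE; reason <- "rate SE exceeds rate"
  }
  structure(list(state = curve$state, start = curve$start, end = curve$end,
                 plateau = unname(est["plateau"]), rate = unname(est["rate"]),
                 rate_se = unname(se["rate"]),
                 t95 = log(20) / unname(est["rate"]),
                 reliable = reliable, reason = reason),
            class = "equilibration_result")
}

#' Map peptide uptake onto residues and flag active-site peptides
#'
#' For each residue covered by at least one peptide, reports the arithmetic
#' mean of corrected uptake over the covering peptides, per exposure time.
#' A peptide is flagged "active-site" iff it contains at least one residue of
#' the supplied shell (e.g. the residues within 4 Angstrom of a bound
#' cofactor or substrate). Peptides extending beyond the structure numbering
#' are flagged and excluded from the residue map.
#'
#' @param curves List of `uptake_curve` objects (one state).
#' @param shell Integer vector of shell residue numbers.
#' @param max_residue Last residue of the structure numbering (`NULL` skips
#'   the bounds check).
#' @return list with `peptides` (identity, active_site flag, excluded flag)
#'   and `residues` (residue, time, mean corrected uptake, n peptides).
#' @export
map_uptake_to_structure <- function(curves, shell, max_residue = NULL) {
  pep <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(start = cv$start, end = cv$end, sequence = cv$sequence,
               active_site = any(seq(cv$start, cv$end) %in% shell),
               excluded = !is.null(max_residue) && cv$end > max_residue,
               stringsAsFactors = FALSE)
  }))
  resrows <- list()
  for (cv in curves) {
    if (!is.null(max_residue) && cv$end > max_residue) next
    for (i in seq_along(cv$times)) {
      resrows[[length(resrows) + 1]] <-
        data.frame(residue = seq(cv$start, cv$end), time = cv$times[i],
                   uptake = cv$corrected_uptake[i])
    }
  }
  residues <- if (length(resrows)) {
    all <- do.call(rbind, resrows)
    agg <- stats::aggregate(uptake ~ residue + time, data = all, FUN = mean)
    n <- stats::aggregate(uptake ~ residue + time, data = all, FUN = length)
    agg$n_peptides <- n$uptake
    agg[order(agg$residue, agg$time), ]
  } else {
    data.frame(residue = integer(), time = numeric(), uptake = numeric(),
               n_peptides = integer())
  }
  list(peptides = pep, residues = residues)
}
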