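#' Read a phase-I reference sample from a single-column CSV
#'
#' @param path CSV file with one numeric column (header optional but
#'   recommended, e.g. `value`).
#' @return Numeric vector.
#' @export
read_phase1 <- function(path) {
  df <- read.csv(path)
  if (ncol(df) < 1L || nrow(df) < 1L)
    stop("empty phase-I file: ", path, call. = FALSE)
  x <- as.numeric(df[[1L]])
  if (!all(is.finite(x)))
    stop("non-finite values in phase-I file: ", path, call. = FALSE)
  x
}

#' Read phase-II subgroups from CSV
#'
#' The primary layout is wide: one subgroup per row with columns
#' `subgroup, obs1..obsn` (any leading index column named `subgroup`,
#' `t` or `sample` is dropped). A long layout with columns
#' `subgroup, value` is accepted with `long = TRUE`.
#'
#' @param path CSV file.
#' @param long logical; use the long layout.
#' @return Numeric matrix, one subgroup per row.
#' @export
read_phase2 <- function(path, long = FALSE) {
  df <- read.csv(path)
  if (nrow(df) < 1L) stop("empty phase-II file: ", path, call. = FALSE)
  if (long) {
    if (ncol(df) < 2L)
      stop("long layout needs columns 'subgroup' and 'value'",
           call. = FALSE)
    idx <- df[[1L]]
    counts <- table(idx)
    if (length(unique(counts)) != 1L)
      stop("ragged subgroups in long phase-II file; subgroup(s) ",
           paste(names(counts)[counts != max(counts)], collapse = ", "),
           " have a different size", call. = FALSE)
    ord <- order(match(idx, unique(idx)))
    mat <- matrix(as.numeric(df[[2L]][ord]), nrow = length(counts),
                  byrow = TRUE)
  } else {
    drop <- names(df) %in% c("subgroup", "t", "sample")
    mat <- as.matrix(df[, !drop, drop = FALSE])
    mode(mat) <- "numeric"
    bad <- rowSums(is.na(mat)) > 0
    if (any(bad))
      stop("ragged or non-numeric phase-II row(s): ",
           paste(which(bad), collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(mat)))
    stop("non-finite values in phase-II file: ", path, call. = FALSE)
  unname(mat)
}

#' Monitor a phase-II stream with one or more rank-sum charts
#'
#' Computes the rank-sum statistic of every phase-II subgroup against
#' the fixed phase-I reference sample and runs each requested scheme
#' over the resulting sequence, producing a per-subgroup table of
#' statistics, control limits and signal flags (the layout of a
#' classical monitoring report).
#'
#' @param phase1 numeric vector or path to a phase-I CSV.
#' @param phase2 numeric matrix (one subgroup per row) or path to a
#'   phase-II CSV.
#' @param specs a [chart_spec()] or a (possibly named) list of them.
#' @param long logical; passed to [read_phase2()] when `phase2` is a
#'   path.
#' @return An object of class `"monitoring_report"`: a list with
#'   `header` (m, n, moments, specs), `w` (the rank-sum sequence),
#'   `tables` (one [apply_chart()] data frame per scheme) and
#'   `first_signal` (smallest signalling subgroup per scheme, `NA` if
#'   none).
#' @examples
#' fx <- make_illustration_fixture(seed = 1)
#' rep <- run_monitoring(fx$phase1, fx$phase2,
#'                       chart_spec("hwma", lambda = 0.5, L = 2.9069))
#' rep$first_signal
#' @export
run_monitoring <- function(phase1, phase2, specs, long = FALSE) {
  if (is.character(phase1)) phase1 <- read_phase1(phase1)
  if (is.character(phase2)) phase2 <- read_phase2(phase2, long = long)
  if (is.vector(phase2)) phase2 <- matrix(phase2, nrow = 1L)
  if (length(phase1) < 1L)
    stop("empty phase-I sample", call. = FALSE)
  if (inherits(specs, "chart_spec")) specs <- list(specs)
  if (!length(specs) || !all(vapply(specs, inherits, logical(1),
                                    "chart_spec")))
    stop("'specs' must be chart_spec objects", call. = FALSE)
  if (is.null(names(specs)) || any(names(specs) == ""))
    names(specs) <- make.unique(vapply(specs, `[[`, character(1),
                                       "scheme"))

  mom <- w_moments(length(phase1), ncol(phase2))
  w <- apply(phase2, 1L, wilcoxon_rank_sum, ref = phase1)
  tables <- lapply(specs, function(s) apply_chart(w, s, mom))
  first_signal <- vapply(tables, function(tb) {
    i <- which(tb$signal)
    if (length(i)) min(i) else NA_integer_
  }, integer(1))
  structure(
    list(header = list(m = mom$m, n = mom$n, moments = mom,
                       specs = specs),
         w = w, tables = tables, first_signal = first_signal),
    class = "monitoring_report"
  )
}

#' @export
print.monitoring_report <- function(x, ...) {
  cat(sprintf("Monitoring report: m = %d, n = %d, %d subgroup(s)\n",
              x$header$m, x$header$n, length(x$w)))
  for (nm in names(x$tables)) {
    fs <- x$first_signal[[nm]]
    cat(sprintf("  %s: first signal at %s\n", nm,
                if (is.na(fs)) "none" else paste("subgroup", fs)))
  }
  invisible(x)
}

#' Round half away from zero
#'
#' Display rounding used in monitoring reports (the convention of
#' printed chart tables), as opposed to [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Write a monitoring report as delimited text
#'
#' One CSV block per scheme with columns `subgroup`, `statistic`,
#' `lcl`, `ucl`, `signal` (values displayed at 2 decimals, half-up;
#' full precision is kept in the in-memory report). Regenerating the
#' file from the same inputs is byte-identical.
#'
#' @param report a [run_monitoring()] result.
#' @param path output file.
#' @param digits display digits (default 2).
#' @return Invisibly, `path`.
#' @export
write_monitoring_report <- function(report, path, digits = 2) {
  stopifnot(inherits(report, "monitoring_report"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  hd <- report$header
  writeLines(sprintf("# m=%d n=%d mu_w=%g sigma_w=%.6f", hd$m, hd$n,
                     hd$moments$mu_w, hd$moments$sigma_w), con)
  for (nm in names(report$tables)) {
    tb <- report$tables[[nm]]
    spec <- hd$specs[[nm]]
    lab <- if (spec$scheme == "hhwma")
      sprintf("lambda1=%g lambda2=%g", spec$l_outer, spec$l_inner)
    else if (spec$scheme == "cusum") sprintf("k=%s",
      if (is.null(spec$k)) "0.5*sigma_w" else format(spec$k))
    else sprintf("lambda=%g", spec$l_outer)
    writeLines(sprintf("# scheme=%s %s L=%g", nm, lab, spec$L), con)
    if (spec$scheme == "cusum") {
      out <- data.frame(subgroup = tb$t,
                        cusum_pos = round_half_up(tb$cusum_pos, digits),
                        cusum_neg = round_half_up(tb$cusum_neg, digits),
                        h = round_half_up(tb$h, digits),
                        signal = tb$signal)
    } else {
      out <- data.frame(subgroup = tb$t,
                        statistic = round_half_up(tb$statistic, digits),
                        lcl = round_half_up(tb$lcl, digits),
                        ucl = round_half_up(tb$ucl, digits),
                        signal = tb$signal)
    }
    write.csv(out, con, row.names = FALSE)
  }
  invisible(path)
}
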