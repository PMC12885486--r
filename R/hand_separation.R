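#' Second-highest-bin location of a binned PDF
#'
#' The TI location (bin centre) of the bin with the second-largest
#' probability mass. With a large rest peak in the bottom bin, this bin
#' tracks where the remaining (tremor-related) mass concentrates. Ties are
#' broken toward the lower-TI bin.
#'
#' @param pdf a `binned_pdf`.
#' @return the bin centre in tiu.
#' @export
second_peak_bin <- function(pdf) {
  stopifnot(inherits(pdf, "binned_pdf"))
  occ <- which(pdf$probabilities > 0)
  if (length(occ) < 2L) {
    stop("degenerate distribution: fewer than 2 occupied bins", call. = FALSE)
  }
  ord <- occ[order(-pdf$probabilities[occ], pdf$centers[occ])]
  pdf$centers[ord[2L]]
}

#' Log distance between the two hands' second peaks
#'
#' `D_f = log10(bin_T) - log10(bin_nT)`, where `bin_T` and `bin_nT` are the
#' second-highest-bin TI locations of the most and least tremor-affected
#' hand on a shared binning grid. Positive values mean the tremor hand's
#' secondary mass sits at higher TI.
#'
#' @param pdf_T,pdf_nT `binned_pdf` objects on the same grid.
#' @return list with `D_f`, `bin_T`, `bin_nT`.
#' @export
hand_distance <- function(pdf_T, pdf_nT) {
  if (!isTRUE(all.equal(pdf_T$edges, pdf_nT$edges))) {
    stop("hands must be binned on a shared grid (same edges)", call. = FALSE)
  }
  bin_T <- second_peak_bin(pdf_T)
  bin_nT <- second_peak_bin(pdf_nT)
  if (bin_T <= 0 || bin_nT <= 0) {
    stop("log-domain error: second-peak location must be positive", call. = FALSE)
  }
  list(D_f = log10(bin_T) - log10(bin_nT), bin_T = bin_T, bin_nT = bin_nT)
}

#' Count of separated frequencies
#'
#' Flags frequency `f` as separated (`c_f = 1`) when the inter-hand
#' second-peak separation reaches 30% of the maximum TI observed at that
#' frequency (both hands pooled), and counts `C = sum(c_f)`. The default
#' `"linear"` rule compares the linear peak distance `bin_T - bin_nT` to
#' `0.3 * max(TI_f)`, keeping both sides of the comparison in tiu; the
#' `"literal"` rule compares the log distance `D_f` itself to the same
#' threshold. The rule applied is recorded in the result.
#'
#' @param distances data.frame with columns `f`, `bin_T`, `bin_nT`, `D_f`
#'   (one row per frequency; NA rows are excluded from C with a warning).
#' @param ti_max named numeric: maximum valid TI per frequency, names
#'   matching `distances$f`.
#' @param rule `"linear"` (default) or `"literal"`.
#' @return list with `c_f` (named 0/1 vector, NA where undefined), `C`,
#'   `threshold_rule`.
#' @export
separated_count <- function(distances, ti_max, rule = c("linear", "literal")) {
  rule <- match.arg(rule)
  tm <- ti_max[as.character(distances$f)]
  stat <- switch(rule,
                 linear = distances$bin_T - distances$bin_nT,
                 literal = distances$D_f)
  c_f <- as.integer(stat >= 0.3 * tm - 1e-12)
  names(c_f) <- as.character(distances$f)
  if (anyNA(c_f)) {
    warning(sprintf("c_f undefined at %d frequencies; excluded from C",
                    sum(is.na(c_f))), call. = FALSE)
  }
  list(c_f = c_f, C = sum(c_f, na.rm = TRUE), threshold_rule = rule)
}

#' Clinical tremor symptom load
#'
#' `L = (number of present tremor types) * (sum of their item intensities)`
#' over the postural, kinetic and rest tremor items of the motor examination
#' (each scored 0-4; a type is present when its intensity exceeds 0). Range
#' 0-36.
#'
#' @param postural,kinetic,rest item intensities, integers 0-4 (vectorised).
#' @return numeric vector of symptom loads.
#' @examples
#' symptom_load(postural = 1, kinetic = 0, rest = 2)  # 2 types x 3 points = 6
#' @export
symptom_load <- function(postural, kinetic, rest) {
  ints <- cbind(postural, kinetic, rest)
  if (any(ints != round(ints)) || any(ints < 0) || any(ints > 4)) {
    stop("tremor item intensities must be integers in 0..4", call. = FALSE)
  }
  rowSums(ints > 0) * rowSums(ints)
}

#' Read per-hand clinical tremor scores
#' @param path CSV with columns `participant_id`, `hand`, `postural`,
#'   `kinetic`, `rest` (intensities 0-4).
#' @return data.frame with an added `L` column.
#' @export
read_clinical_scores <- function(path) {
  sc <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "hand", "postural", "kinetic", "rest")
  if (!all(need %in% names(sc))) {
    stop(sprintf("clinical CSV must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  sc$L <- symptom_load(sc$postural, sc$kinetic, sc$rest)
  sc
}

#' Inter-hand separation analysis for one participant
#'
#' Pools valid TI windows per frequency for each hand, bins both hands on a
#' shared grid over the pooled maximum, and computes the second-peak
#' locations, the log distance `D_f`, the separation flags and the count C.
#'
#' @param profile_T,profile_nT TI profiles (from [ti_profile()]) of the most
#'   and least tremor-affected hand.
#' @param nbins histogram bins (default 20).
#' @param rule separation rule, see [separated_count()].
#' @return a `separation_result`: data.frame with `f`, `bin_T`, `bin_nT`,
#'   `D_f`, `c_f`, `ti_max`; attributes `C` and `threshold_rule`.
#' @export
separate_hands <- function(profile_T, profile_nT, nbins = 20,
                           rule = c("linear", "literal")) {
  rule <- match.arg(rule)
  fs <- intersect(names(profile_T), names(profile_nT))
  if (length(fs) == 0L) stop("profiles share no frequencies", call. = FALSE)
  rows <- list()
  for (nm in fs) {
    f <- attr(profile_T[[nm]], "f")
    vT <- valid_ti(profile_T[[nm]])
    vnT <- valid_ti(profile_nT[[nm]])
    row <- data.frame(f = f, bin_T = NA_real_, bin_nT = NA_real_,
                      D_f = NA_real_, ti_max = NA_real_)
    if (length(vT) > 0L && length(vnT) > 0L) {
      tm <- max(vT, vnT)
      row$ti_max <- tm
      hd <- tryCatch({
        pT <- ti_histogram(vT, nbins, ti_max = tm)
        pnT <- ti_histogram(vnT, nbins, ti_max = tm)
        hand_distance(pT, pnT)
      }, error = function(e) NULL)
      if (!is.null(hd)) {
        row$bin_T <- hd$bin_T; row$bin_nT <- hd$bin_nT; row$D_f <- hd$D_f
      }
    }
    rows[[length(rows) + 1L]] <- row
  }
  tbl <- do.call(rbind, rows)
  tm <- stats::setNames(tbl$ti_max, as.character(tbl$f))
  sc <- separated_count(tbl, tm, rule)
  tbl$c_f <- unname(sc$c_f)
  structure(tbl, C = sc$C, threshold_rule = sc$threshold_rule,
            class = c("separation_result", "data.frame"))
}

#' @export
print.separation_result <- function(x, ...) {
  cat(sprintf("<separation_result> C = %d separated frequencies (rule: %s)\n",
              attr(x, "C"), attr(x, "threshold_rule")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Association between separated-frequency count and symptom load
#'
#' Normalises the per-participant counts C and loads L to a common 0-10
#' scale using their theoretical maxima (the size of the frequency set, and
#' 36), then computes the Pearson correlation, the mean of the `C - L`
#' differences with its 95% t-interval, and a paired-samples t-test.
#'
#' @param C integer vector of separated-frequency counts, one per
#'   participant.
#' @param L numeric vector of symptom loads, aligned with `C`.
#' @param n_freqs size of the frequency set used for C (default 10).
#' @param l_max theoretical maximum load (default 36).
#' @return an `association_result`: `pearson_r`, `pearson_p`, `mean_diff`,
#'   `ci95`, `ttest_p`, `n`.
#' @export
associate <- function(C, L, n_freqs = 10, l_max = 36) {
  if (length(C) != length(L)) stop("C and L must be aligned", call. = FALSE)
  if (length(C) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  Cn <- C * 10 / n_freqs
  Ln <- L * 10 / l_max
  if (stats::sd(Cn) == 0 || stats::sd(Ln) == 0) {
    stop("correlation undefined: zero variance in C or L", call. = FALSE)
  }
  ct <- stats::cor.test(Cn, Ln, method = "pearson")
  d <- Cn - Ln
  tt <- if (stats::sd(d) == 0) NULL else stats::t.test(d)
  structure(list(
    pearson_r = unname(ct$estimate), pearson_p = ct$p.value,
    mean_diff = mean(d),
    ci95 = if (is.null(tt)) c(mean(d), mean(d)) else as.numeric(tt$conf.int),
    ttest_p = if (is.null(tt)) 1 else tt$p.value,
    n = length(C)), class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(
    "<association_result> n=%d: r = %.3f (p = %.3g); mean C-L = %.3f, 95%% CI [%.3f, %.3f], paired t p = %.3g\n",
    x$n, x$pearson_r, x$pearson_p, x$mean_diff, x$ci95[1L], x$ci95[2L], x$ttest_p))
  invisible(x)
}
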