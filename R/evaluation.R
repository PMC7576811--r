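#' Score a batch of spectrum pairs
#'
#' Computes both match factors for every (prediction, reference) pair and
#' joins optional compound metadata and flexibility descriptors into one
#' evaluation table — the row type all batch statistics operate on.
#'
#' @param pairs list of pairs; each element a list with a prediction
#'   spectrum (`pred` or `query`), a reference spectrum (`ref` or
#'   `reference`) and an `id`. [gen_pairs()] output works directly.
#' @param metadata optional data frame with column `id` and any of
#'   `inchikey`, `mw`, `class`, `rbn`, `phi`, `molfile_path`. Ids must
#'   match pair ids 1:1; when `molfile_path` is present the descriptors
#'   are computed from the Molfile, otherwise `rbn`/`phi` are copied.
#' @param m,n weighted dot-product exponents, see [weighted_dot_score()].
#' @return Object of class `eims_eval`: a data frame with columns `id`,
#'   `inchikey`, `mw`, `class_label`, `rbn`, `phi`, `dot`, `cos`.
#' @export
evaluate_batch <- function(pairs, metadata = NULL, m = 0.6, n = 3) {
  stopifnot(is.list(pairs), length(pairs) > 0)
  get1 <- function(p, a, b) if (!is.null(p[[a]])) p[[a]] else p[[b]]
  ids <- vapply(seq_along(pairs), function(k) {
    id <- pairs[[k]]$id
    if (is.null(id)) sprintf("pair%04d", k) else as.character(id)
  }, character(1))
  scores <- t(vapply(pairs, function(p) {
    score_pair(get1(p, "pred", "query"), get1(p, "ref", "reference"),
               m = m, n = n)
  }, numeric(2)))
  rec <- data.frame(id = ids, inchikey = NA_character_, mw = NA_real_,
                    class_label = NA_character_, rbn = NA_real_,
                    phi = NA_real_, dot = as.integer(scores[, "dot"]),
                    cos = as.integer(scores[, "cos"]),
                    stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (!"id" %in% names(metadata))
      stop("metadata must have an 'id' column", call. = FALSE)
    idx <- match(rec$id, as.character(metadata$id))
    if (anyNA(idx))
      stop("integrity error: pair ids missing from metadata: ",
           paste(utils::head(rec$id[is.na(idx)], 5L), collapse = ", "),
           call. = FALSE)
    md <- metadata[idx, ]
    if ("inchikey" %in% names(md)) rec$inchikey <- as.character(md$inchikey)
    if ("mw" %in% names(md)) rec$mw <- as.numeric(md$mw)
    if ("class" %in% names(md)) rec$class_label <- as.character(md$class)
    if ("molfile_path" %in% names(md)) {
      g <- lapply(md$molfile_path, read_molfile)
      rec$rbn <- vapply(g, rotatable_bond_count, numeric(1))
      rec$phi <- vapply(g, function(x) kappa_indices(x)$phi, numeric(1))
    } else {
      if ("rbn" %in% names(md)) rec$rbn <- as.numeric(md$rbn)
      if ("phi" %in% names(md)) rec$phi <- as.numeric(md$phi)
    }
  }
  class(rec) <- c("eims_eval", "data.frame")
  rec
}

#' Summary statistics of a score distribution
#'
#' For each match factor separately: n, mean, median, sample standard
#' deviation (n-1 denominator; absent for a single record), and the three
#' conventional GC-MS threshold fractions: scores above 700 (good match),
#' above 850 (identification grade), and below 500 (usually discarded).
#' All strict inequalities.
#'
#' @param records an `eims_eval` table (or any data frame with `dot` and
#'   `cos` columns).
#' @return Data frame with one row per score type (`dot`, `cos`) and
#'   columns `score`, `n`, `mean`, `median`, `sd`, `frac_gt700`,
#'   `frac_gt850`, `frac_lt500`.
#' @export
summarize_scores <- function(records) {
  stopifnot(all(c("dot", "cos") %in% names(records)))
  one <- function(x, label) {
    data.frame(score = label, n = length(x), mean = mean(x),
               median = stats::median(x),
               sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
               frac_gt700 = mean(x > 700), frac_gt850 = mean(x > 850),
               frac_lt500 = mean(x < 500), stringsAsFactors = FALSE)
  }
  rbind(one(records$dot, "dot"), one(records$cos, "cos"))
}

#' @export
summary.eims_eval <- function(object, ...) summarize_scores(object)

#' @export
print.eims_eval <- function(x, ...) {
  cat("Batch evaluation:", nrow(x), "compound records\n")
  s <- summarize_scores(x)
  cat(sprintf("  %s: mean %.0f, median %.0f, >700 %.0f%%, >850 %.0f%%, <500 %.0f%%\n",
              s$score, s$mean, s$median, 100 * s$frac_gt700,
              100 * s$frac_gt850, 100 * s$frac_lt500))
  invisible(x)
}

#' Compare score distributions between compound classes
#'
#' Welch two-sample t-tests (two-sided) of each eligible class against a
#' reference class. A class is eligible when it has at least `min_n`
#' records (default 50, below which group comparisons are considered not
#' robust). The reference defaults to the eligible class with the lowest
#' mean score, so each row reports how much better (or worse) a class
#' fares than the weakest one.
#'
#' @param records an `eims_eval` table with a `class_label` column.
#' @param score `"dot"` or `"cos"`.
#' @param min_n minimum class size for eligibility.
#' @param reference_class reference class label; default the lowest-mean
#'   eligible class.
#' @param p_adjust if `TRUE`, add Benjamini-Hochberg adjusted p-values.
#' @return Data frame with columns `class_a` (reference), `class_b`,
#'   `n_a`, `n_b`, `mean_a`, `mean_b`, `statistic`, `p_value`, `test`
#'   (and `p_adj` when requested); zero rows with a warning when fewer
#'   than two classes are eligible.
#' @export
compare_classes <- function(records, score = c("dot", "cos"), min_n = 50,
                            reference_class = NULL, p_adjust = FALSE) {
  score <- match.arg(score)
  x <- records[[score]]
  cls <- as.character(records$class_label)
  ok <- !is.na(cls)
  x <- x[ok]; cls <- cls[ok]
  sizes <- table(cls)
  eligible <- names(sizes)[sizes >= min_n]
  empty <- data.frame(class_a = character(), class_b = character(),
                      n_a = integer(), n_b = integer(),
                      mean_a = numeric(), mean_b = numeric(),
                      statistic = numeric(), p_value = numeric(),
                      test = character(), stringsAsFactors = FALSE)
  if (length(eligible) < 2L) {
    warning("fewer than two classes with n >= ", min_n,
            "; no comparisons computed")
    return(empty)
  }
  means <- vapply(eligible, function(cl) mean(x[cls == cl]), numeric(1))
  ref <- if (is.null(reference_class)) eligible[which.min(means)]
         else as.character(reference_class)
  if (!ref %in% eligible)
    stop("reference class '", ref, "' is not eligible", call. = FALSE)
  others <- setdiff(eligible, ref)
  out <- do.call(rbind, lapply(others, function(cl) {
    tt <- stats::t.test(x[cls == cl], x[cls == ref],
                        alternative = "two.sided", var.equal = FALSE)
    data.frame(class_a = ref, class_b = cl,
               n_a = sum(cls == ref), n_b = sum(cls == cl),
               mean_a = mean(x[cls == ref]), mean_b = mean(x[cls == cl]),
               statistic = unname(tt$statistic), p_value = tt$p.value,
               test = "Welch two-sample t-test (two-sided)",
               stringsAsFactors = FALSE)
  }))
  if (p_adjust) out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Rank correlation of flexibility descriptors with match factors
#'
#' Spearman rank correlations of PHI and RBN against both scores, used to
#' ask whether conformational flexibility predicts how well a spectrum was
#' predicted. A constant (or absent) descriptor yields NA.
#'
#' @param records an `eims_eval` table with `phi` and `rbn` columns.
#' @return Data frame with columns `descriptor`, `score`, `rho`,
#'   `p_value`, `n`.
#' @export
correlate_flexibility <- function(records) {
  grid <- expand.grid(descriptor = c("phi", "rbn"),
                      score = c("dot", "cos"), stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(grid)), function(k) {
    d <- records[[grid$descriptor[k]]]
    s <- records[[grid$score[k]]]
    ok <- !is.na(d) & !is.na(s)
    res <- data.frame(descriptor = grid$descriptor[k],
                      score = grid$score[k], rho = NA_real_,
                      p_value = NA_real_, n = sum(ok),
                      stringsAsFactors = FALSE)
    if (sum(ok) >= 3L && length(unique(d[ok])) > 1L &&
        length(unique(s[ok])) > 1L) {
      ct <- suppressWarnings(
        stats::cor.test(d[ok], s[ok], method = "spearman"))
      res$rho <- unname(ct$estimate)
      res$p_value <- ct$p.value
    }
    res
  }))
}

#' Summarize a parameter sweep
#'
#' Aggregates evaluation tables keyed by a parameter value (e.g. number of
#' trajectories, impact excess energy per atom, or initial temperature)
#' into one table of mean scores per setting, sorted by the parameter.
#'
#' @param sets named list of `eims_eval` tables; names are the parameter
#'   values.
#' @param parameter label for the swept parameter column.
#' @return Data frame with columns `parameter`, `value`, `n`, `mean_dot`,
#'   `mean_cos`, sorted by `value` (numerically when possible).
#' @export
sweep_summarize <- function(sets, parameter = "parameter") {
  if (length(sets) == 0L)
    stop("sweep_summarize: no record sets given", call. = FALSE)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named by parameter value", call. = FALSE)
  out <- do.call(rbind, lapply(names(sets), function(v) {
    s <- summarize_scores(sets[[v]])
    data.frame(parameter = parameter, value = v, n = s$n[1],
               mean_dot = s$mean[s$score == "dot"],
               mean_cos = s$mean[s$score == "cos"],
               stringsAsFactors = FALSE)
  }))
  num <- suppressWarnings(as.numeric(out$value))
  out[order(if (anyNA(num)) out$value else num), , drop = FALSE]
}
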