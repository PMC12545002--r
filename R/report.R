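#' Pool a ratings table into one call vector
#'
#' Stacks the `k` raters' calls into a single vector of `k * n` observations
#' with the truth replicated, the pooling under which a panel's binary-call
#' AUC is estimated.
#'
#' @param ratings a `ratings_table`.
#' @return A list with `calls` and `truth`.
#' @export
pool_ratings <- function(ratings) {
  m <- ratings_matrix(ratings)
  list(calls = as.vector(m), truth = rep(ratings$truth, ncol(m)))
}

# correctness (call == truth) per rater, stacked; used by the paired test
correctness <- function(ratings) {
  m <- ratings_matrix(ratings)
  as.vector(m == ratings$truth) * 1L
}

#' Full reader-study statistical report
#'
#' Reproduces the reader-study battery over a set of reading sessions:
#' pooled and per-rater-averaged diagnostic metrics per session, the
#' within-group ICC (two-way random, absolute agreement) per session, Fleiss'
#' kappa over each session's panel plus pairwise Cohen's kappa between
#' session majority calls, the McNemar paired test on correctness for each
#' `unassisted -> assisted` pairing, and the DeLong test on the pooled AUCs
#' of each pairing.
#'
#' @param sessions named list of `ratings_table` objects (e.g.
#'   `junior_unassisted`, `junior_assisted`, ...). All sessions must share
#'   the same `case_id` and `truth`.
#' @param pairings named character vector mapping unassisted to assisted
#'   session names, e.g. `c(junior_unassisted = "junior_assisted")`. Default:
#'   every pair of names differing only in an `unassisted`/`assisted` suffix.
#' @param ci_method proportion CI method, passed to [diagnostic_metrics()].
#' @return A `reader_study_report` list of tibbles: `performance`,
#'   `performance_by_rater`, `icc`, `fleiss`, `pairwise_kappa`, `mcnemar`,
#'   `delong`. No multiplicity adjustment is applied (`meta$p_adjust`).
#' @export
reader_study_report <- function(sessions, pairings = NULL,
                                ci_method = "clopper-pearson") {
  stopifnot(is.list(sessions), length(sessions) >= 1,
            !is.null(names(sessions)))
  ids <- lapply(sessions, function(s) s$case_id)
  for (nm in names(sessions)[-1]) {
    if (!identical(ids[[1]], ids[[nm]])) {
      stop("sessions do not share case_ids; offender: '", nm, "'",
           call. = FALSE)
    }
  }
  truths <- lapply(sessions, function(s) s$truth)
  for (nm in names(sessions)[-1]) {
    if (!identical(truths[[1]], truths[[nm]])) {
      stop("sessions disagree on ground truth; offender: '", nm, "'",
           call. = FALSE)
    }
  }
  if (is.null(pairings)) {
    un <- grep("unassisted", names(sessions), value = TRUE)
    pairings <- stats::setNames(sub("unassisted", "assisted", un), un)
    pairings <- pairings[pairings %in% names(sessions)]
  }

  performance <- purrr::imap_dfr(sessions, function(s, nm) {
    p <- pool_ratings(s)
    dplyr::mutate(tidy(diagnostic_metrics(p$calls, p$truth,
                                          ci_method = ci_method)),
                  session = nm, pooling = "pooled", .before = 1)
  })
  performance_by_rater <- purrr::imap_dfr(sessions, function(s, nm) {
    m <- ratings_matrix(s)
    per <- purrr::map_dfr(seq_len(ncol(m)), function(j) {
      dplyr::mutate(tidy(diagnostic_metrics(m[, j], s$truth,
                                            ci_method = ci_method)),
                    rater = j)
    })
    avg <- dplyr::summarise(dplyr::group_by(per, .data$metric),
                            estimate = mean(.data$estimate), .groups = "drop")
    dplyr::mutate(avg, session = nm, pooling = "rater_averaged", .before = 1)
  })
  icc <- purrr::imap_dfr(sessions, function(s, nm) {
    dplyr::mutate(tidy(icc_absolute(s)), session = nm, .before = 1)
  })
  fleiss <- purrr::imap_dfr(sessions, function(s, nm) {
    dplyr::mutate(tidy(fleiss_kappa(s)), session = nm, .before = 1)
  })

  majority <- lapply(sessions, function(s) {
    m <- ratings_matrix(s)
    as.integer(rowMeans(m) >= 0.5)
  })
  nm <- names(sessions)
  pairwise_kappa <- if (length(nm) >= 2) {
    purrr::map_dfr(utils::combn(nm, 2, simplify = FALSE), function(pr) {
      # Fleiss over the two sessions' pooled panel + Cohen on majority calls
      pooled <- cbind(ratings_matrix(sessions[[pr[1]]]),
                      ratings_matrix(sessions[[pr[2]]]))
      fk <- fleiss_kappa(pooled)
      ck <- cohen_kappa(majority[[pr[1]]], majority[[pr[2]]])
      tibble::tibble(session_a = pr[1], session_b = pr[2],
                     fleiss_pooled = fk$kappa,
                     cohen_majority = ck$estimate,
                     cohen_conf.low = ck$conf.low,
                     cohen_conf.high = ck$conf.high)
    })
  } else tibble::tibble()

  mcnemar <- purrr::imap_dfr(pairings, function(to, from) {
    dplyr::mutate(tidy(mcnemar_paired(correctness(sessions[[to]]),
                                      correctness(sessions[[from]]))),
                  unassisted = from, assisted = to, .before = 1)
  })
  delong <- purrr::imap_dfr(pairings, function(to, from) {
    pa <- pool_ratings(sessions[[to]])
    pb <- pool_ratings(sessions[[from]])
    dplyr::mutate(tidy(delong_compare(pa$calls, pb$calls, pa$truth)),
                  unassisted = from, assisted = to, .before = 1)
  })

  structure(list(performance = performance,
                 performance_by_rater = performance_by_rater,
                 icc = icc, fleiss = fleiss,
                 pairwise_kappa = pairwise_kappa,
                 mcnemar = mcnemar, delong = delong,
                 meta = list(p_adjust = "none", ci_method = ci_method)),
            class = "reader_study_report")
}

#' @export
print.reader_study_report <- function(x, ...) {
  cat("<reader_study_report>\n\nPooled diagnostic performance:\n")
  print(tidyr::pivot_wider(
    dplyr::select(x$performance, "session", "metric", "estimate"),
    names_from = "metric", values_from = "estimate"))
  cat("\nWithin-group ICC (two-way random, absolute agreement):\n")
  print(dplyr::select(x$icc, "session", "estimate", "conf.low", "conf.high"))
  if (nrow(x$mcnemar)) {
    cat("\nMcNemar on correctness (assisted vs unassisted):\n")
    print(x$mcnemar)
  }
  invisible(x)
}

#' Compute worked-example percentages from a cohort count table
#'
#' Takes a table of counts with explicit denominators (columns `item`,
#' `count`, `denominator`, where `denominator` names another `item`) and
#' returns each count as a percentage of its denominator. A cohort summary in
#' this form ships in `inst/extdata/example_cohort_counts.csv`.
#'
#' @param counts data frame with columns `item`, `count`, `denominator`.
#' @return Tibble with columns `item`, `count`, `denominator_n`, `pct`
#'   (percentage, one decimal as conventionally printed) and `pct_exact`.
#' @export
cohort_proportions <- function(counts) {
  stopifnot(all(c("item", "count", "denominator") %in% names(counts)))
  den_n <- counts$count[match(counts$denominator, counts$item)]
  out <- tibble::tibble(item = counts$item, count = counts$count,
                        denominator_n = den_n,
                        pct_exact = 100 * counts$count / den_n)
  dplyr::mutate(out, pct = round(.data$pct_exact, 1), .before = "pct_exact")
}
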