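#' Bedside hematoma volume estimate
#'
#' ABC-style volume from three orthogonal CT diameters: the ellipsoid
#' approximation `length x width x depth / 2` for regular clots, and
#' `length x width x depth / 3` for irregular clots.
#'
#' @param length,width,depth clot diameters, cm (vectorized).
#' @param shape `"regular"` or `"irregular"` (recycled).
#' @return volume in cm^3.
#' @export
hematoma_volume <- function(length, width, depth,
                            shape = c("regular", "irregular")) {
  if (any(c(length, width, depth) < 0)) stop_nm("dimensions must be non-negative")
  shape <- match.arg(shape, several.ok = TRUE)
  shape <- rep(shape, length.out = max(base::length(length), base::length(width),
                                       base::length(depth)))
  length * width * depth / ifelse(shape == "regular", 2, 3)
}

#' Apply eligibility screening
#'
#' Removes every roster record carrying at least one exclusion flag and
#' itemizes the losses per criterion in protocol order. A record with
#' several flags is counted once, under its first-listed criterion.
#' The operation is idempotent: enrolled records carry no flags.
#'
#' @param roster data.frame with one logical column per criterion in
#'   [exclusion_criteria()] (as built by [gen_screening_roster()]).
#' @return list with `enrolled` (flag-free records), `tally` (named counts
#'   per criterion), `n_screened`, `n_enrolled`, `n_excluded`.
#' @export
apply_eligibility <- function(roster) {
  crits <- exclusion_criteria()
  miss <- setdiff(crits, names(roster))
  if (length(miss)) stop_nm("roster lacks flag column(s): ",
                            paste(miss, collapse = ", "))
  flags <- as.matrix(as.data.frame(roster)[, crits])
  first <- apply(flags, 1, function(r) {
    w <- which(r)
    if (length(w)) w[1] else NA_integer_
  })
  tally <- stats::setNames(tabulate(first, nbins = length(crits)), crits)
  enrolled <- roster[is.na(first), , drop = FALSE]
  list(enrolled = enrolled, tally = tally,
       n_screened = nrow(roster), n_enrolled = nrow(enrolled),
       n_excluded = sum(tally))
}

#' Univariate prognostic screen
#'
#' Compares every candidate variable between outcome groups with the test
#' a clinical analyst would pick: Pearson chi-squared without continuity
#' correction for binary variables, Student's t test for continuous
#' variables that pass a Shapiro-Wilk normality gate in both groups
#' (alpha = 0.05), and the Wilcoxon rank-sum test otherwise. Variables
#' with p at or below `selection_alpha` are selected for the multivariable
#' model. Zero-variance variables are flagged and skipped.
#'
#' @param records cohort data.frame.
#' @param vars variable names to screen; defaults to every column except
#'   `id` and the outcome.
#' @param outcome name of the logical/binary outcome column (default
#'   `"died90"`).
#' @param selection_alpha selection threshold on the two-sided p
#'   (default 0.001).
#' @param normality_alpha Shapiro-Wilk gate (default 0.05).
#' @param correct apply Yates continuity correction to chi-squared
#'   (default FALSE).
#' @return data.frame of class `univariate_screen`: `variable`, `test`,
#'   `statistic`, `p`, `selected`.
#' @export
univariate_screen <- function(records, vars = NULL, outcome = "died90",
                              selection_alpha = 0.001, normality_alpha = 0.05,
                              correct = FALSE) {
  if (!outcome %in% names(records)) stop_nm("outcome column not found: ", outcome)
  y <- as.logical(records[[outcome]])
  if (length(unique(y[!is.na(y)])) != 2 || min(table(y)) < 2)
    stop_nm("need at least 2 records in each outcome group")
  vars <- vars %||% setdiff(names(records), c("id", outcome))
  rows <- lapply(vars, function(v) {
    x <- records[[v]]
    is_binary <- is.logical(x) || is.factor(x) ||
      (is.numeric(x) && all(x %in% 0:1))
    if (length(unique(x)) < 2) {
      warning("zero-variance variable skipped: ", v)
      return(data.frame(variable = v, test = "skipped",
                        statistic = NA_real_, p = NA_real_, selected = FALSE))
    }
    if (is_binary) {
      tab <- table(factor(as.logical(x), c(FALSE, TRUE)), y)
      ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
      data.frame(variable = v, test = "chi-squared",
                 statistic = unname(ht$statistic), p = ht$p.value,
                 selected = ht$p.value <= selection_alpha)
    } else {
      g0 <- x[!y]; g1 <- x[y]
      normal <- function(g) {
        if (length(unique(g)) < 3) return(FALSE)
        stats::shapiro.test(g)$p.value > normality_alpha
      }
      if (normal(g0) && normal(g1)) {
        ht <- stats::t.test(g0, g1, var.equal = TRUE)
        data.frame(variable = v, test = "t",
                   statistic = unname(ht$statistic), p = ht$p.value,
                   selected = ht$p.value <= selection_alpha)
      } else {
        ht <- suppressWarnings(stats::wilcox.test(g0, g1))
        data.frame(variable = v, test = "rank",
                   statistic = unname(ht$statistic), p = ht$p.value,
                   selected = ht$p.value <= selection_alpha)
      }
    }
  })
  out <- do.call(rbind, rows)
  out$selected[is.na(out$selected)] <- FALSE
  class(out) <- c("univariate_screen", "data.frame")
  out
}
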