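# ADME screening: Tanimoto drug-likeness, the OB/DL threshold rule with
# literature rescue, and Lipinski rule-of-five flags.

#' Tanimoto coefficient between two descriptor vectors
#'
#' Continuous-vector Tanimoto similarity,
#' \deqn{T(A,B) = \frac{A \cdot B}{|A|^2 + |B|^2 - A \cdot B},}
#' the similarity measure behind the database-dependent drug-likeness score:
#' `A` holds a compound's molecular descriptors and `B` the average
#' descriptors of known drugs.  Symmetric, and equal to 1 exactly when the
#' two (nonzero) vectors coincide.  For non-negative inputs the value lies
#' in \[0, 1\]; with negative components (CLogP can be negative) it can in
#' principle leave that interval, which is accepted and documented rather
#' than clipped.
#'
#' @param a,b Equal-length numeric vectors.  If both carry names, the names
#'   must agree element-wise (label-aligned descriptors).
#' @return The Tanimoto coefficient, a single number.
#' @examples
#' tanimoto(c(1, 0), c(1, 1))  # 0.5
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    stop("descriptor vectors differ in length", call. = FALSE)
  }
  if (!is.null(names(a)) && !is.null(names(b)) && !identical(names(a), names(b))) {
    stop("descriptor labels are not aligned", call. = FALSE)
  }
  if (anyNA(a) || anyNA(b)) stop("missing descriptor values", call. = FALSE)
  ab <- sum(a * b)
  denom <- sum(a^2) + sum(b^2) - ab
  if (denom == 0 && ab == 0) {
    stop("Tanimoto undefined for two all-zero vectors", call. = FALSE)
  }
  ab / denom
}

#' Drug-likeness of a compound relative to a drug reference
#'
#' DL is the Tanimoto coefficient between a compound's descriptor vector and
#' the mean descriptor vector of a drug reference set.  The default
#' reference is the column mean of a small packaged synthetic drug-like
#' descriptor table (MW, CLogP, nHDon, nHAcc); pass `reference_mean` to use
#' your own basis — the score is defined for any label-aligned descriptor
#' vectors, not only the four shipped properties.
#'
#' @param compound Numeric descriptor vector.
#' @param reference_mean Numeric vector of the same length/labels; defaults
#'   to [drug_reference_mean()].
#' @return The DL score.
#' @export
drug_likeness <- function(compound, reference_mean = drug_reference_mean()) {
  if (is.null(names(compound)) && !is.null(names(reference_mean)) &&
      length(compound) == length(reference_mean)) {
    names(compound) <- names(reference_mean)
  }
  tanimoto(compound, reference_mean)
}

#' Mean descriptor vector of the packaged synthetic drug reference
#'
#' Column means (MW, CLogP, nHDon, nHAcc) of
#' `inst/extdata/drug_reference_synthetic.csv`, a small synthetic table of
#' drug-like descriptor values that stands in for a curated drug database
#' when none is supplied.
#'
#' @return Named numeric vector of length 4.
#' @export
drug_reference_mean <- function() {
  path <- system.file("extdata", "drug_reference_synthetic.csv",
                      package = "herbnp")
  ref <- read.csv(path, stringsAsFactors = FALSE)
  colMeans(ref[, c("mw", "clogp", "nhdon", "nhacc")])
}

#' Screen ingredients by oral bioavailability and drug-likeness
#'
#' Partitions an ingredient table into three disjoint, exhaustive groups:
#' `passed` (OB >= `ob_min` and DL >= `dl_min`, both comparisons inclusive),
#' `rescued` (fails at least one threshold — or has a missing OB/DL — but
#' carries the literature-rescue flag), and `excluded` (everything else).
#' An ingredient with missing OB or DL can never pass on numbers alone;
#' rescue is an explicit input flag because the underlying judgement
#' ("profound pharmacological effects and high contents") is a literature
#' call, not a computable rule.
#'
#' @param ingredients Ingredient data frame (see [read_ingredients()]).
#' @param ob_min OB threshold in percent, default 30, within \[0, 100\].
#' @param dl_min DL threshold, default 0.18, within \[0, 1\].
#' @return A `screen_result`: list with character vectors `passed`,
#'   `rescued`, `excluded`, the thresholds used, and an `audit` data frame
#'   recording per ingredient its OB/DL values, per-rule outcomes and the
#'   classification reason.
#' @examples
#' ing <- fixture_paper_tables()$ingredients
#' sr <- screen_ingredients(ing)
#' length(sr$passed) + length(sr$rescued)  # all 43 actives survive
#' @export
screen_ingredients <- function(ingredients, ob_min = 30, dl_min = 0.18) {
  stopifnot(is.finite(ob_min), is.finite(dl_min))
  if (ob_min < 0 || ob_min > 100) stop("ob_min must be in [0, 100]",
                                       call. = FALSE)
  if (dl_min < 0 || dl_min > 1) stop("dl_min must be in [0, 1]",
                                     call. = FALSE)
  ob <- ingredients$ob
  dl <- ingredients$dl
  ob_pass <- !is.na(ob) & ob >= ob_min
  dl_pass <- !is.na(dl) & dl >= dl_min
  both <- ob_pass & dl_pass
  rescued <- !both & ingredients$rescue
  excluded <- !both & !rescued
  reason <- ifelse(both, "meets both thresholds",
            ifelse(rescued, "below threshold, literature-rescued",
                   "below threshold, not rescued"))
  audit <- data.frame(ingredient_id = ingredients$ingredient_id,
                      ob = ob, dl = dl,
                      ob_pass = ob_pass, dl_pass = dl_pass,
                      status = ifelse(both, "passed",
                               ifelse(rescued, "rescued", "excluded")),
                      reason = reason, stringsAsFactors = FALSE)
  structure(list(passed = ingredients$ingredient_id[both],
                 rescued = ingredients$ingredient_id[rescued],
                 excluded = ingredients$ingredient_id[excluded],
                 ob_min = ob_min, dl_min = dl_min, audit = audit),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("ADME screen (OB >= %g%%, DL >= %g)\n", x$ob_min, x$dl_min))
  cat(sprintf("  passed:   %d\n  rescued:  %d\n  excluded: %d\n",
              length(x$passed), length(x$rescued), length(x$excluded)))
  invisible(x)
}

#' @export
summary.screen_result <- function(object, ...) {
  print(object)
  invisible(object$audit)
}

#' Lipinski rule-of-five flags for one ingredient
#'
#' Evaluates MW <= 500, CLogP <= 5, nHDon <= 5, nHAcc <= 10.  A missing
#' descriptor leaves that rule indeterminate (`NA`); the overall verdict
#' uses the standard "at most one violation" formulation, counted over the
#' determinate rules only.
#'
#' @param ingredient One-row ingredient data frame, or a list with fields
#'   `mw`, `clogp`, `nhdon`, `nhacc`.
#' @return List with logicals `mw_ok`, `clogp_ok`, `nhdon_ok`, `nhacc_ok`
#'   (possibly `NA`), the violation count, and `pass`.
#' @export
lipinski_flags <- function(ingredient) {
  val <- function(f) {
    v <- ingredient[[f]]
    if (is.null(v) || length(v) == 0L) NA_real_ else as.numeric(v[1L])
  }
  rules <- c(mw_ok = val("mw") <= 500,
             clogp_ok = val("clogp") <= 5,
             nhdon_ok = val("nhdon") <= 5,
             nhacc_ok = val("nhacc") <= 10)
  violations <- sum(!rules, na.rm = TRUE)
  list(mw_ok = unname(rules["mw_ok"]), clogp_ok = unname(rules["clogp_ok"]),
       nhdon_ok = unname(rules["nhdon_ok"]),
       nhacc_ok = unname(rules["nhacc_ok"]),
       violations = violations, pass = violations <= 1L)
}
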