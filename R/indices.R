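# ---- input validation helpers -----------------------------------------------

# Positive, finite, numeric. `field` names the offending argument in errors so
# that unit mix-ups surface immediately instead of propagating as NaN.
check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) == 0L) {
    stop("invalid input: '", field, "' must be a non-empty numeric vector",
         call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("invalid input: '", field, "' contains missing or non-finite values",
         call. = FALSE)
  }
  if (any(x <= 0)) {
    stop("invalid input: '", field, "' must be strictly positive",
         call. = FALSE)
  }
  invisible(x)
}

check_finite <- function(x, field) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(!is.finite(x))) {
    stop("invalid input: '", field, "' must be finite numeric", call. = FALSE)
  }
  invisible(x)
}

#' Surrogate index kinds and their ROC orientation
#'
#' The package computes eight surrogate measures of insulin sensitivity.
#' Each kind carries an orientation: for resistance-type indices
#' (HOMA-IR, FIRI, fasting insulin/glucose ratio) larger values mean *more*
#' insulin resistant, while for sensitivity-type indices (QUICKI, Matsuda,
#' Stumvoll, revised QUICKI, glucose/insulin ratio) larger values mean *more*
#' insulin sensitive. The orientation determines which direction of a score
#' is treated as "positive" (insulin resistant) in ROC analysis.
#'
#' @return `index_kinds()` returns the character vector of supported kinds in
#'   canonical order. `index_orientation()` returns `"resistance_up"` or
#'   `"sensitivity_up"` for each kind supplied.
#' @examples
#' index_kinds()
#' index_orientation("quicki")
#' @export
index_kinds <- function() {
  c("homa_ir", "quicki", "firi", "matsuda", "stumvoll",
    "revised_quicki", "insulin_glucose_ratio", "glucose_insulin_ratio")
}

#' @param kind character vector of index kinds (see `index_kinds()`).
#' @rdname index_kinds
#' @export
index_orientation <- function(kind) {
  kind <- match.arg(kind, index_kinds(), several.ok = TRUE)
  resistance_up <- c("homa_ir", "firi", "insulin_glucose_ratio")
  ifelse(kind %in% resistance_up, "resistance_up", "sensitivity_up")
}

# ---- fasting indices --------------------------------------------------------

#' Fasting surrogate indices of insulin sensitivity
#'
#' Compute the three interchangeable fasting indices from fasting plasma
#' glucose and fasting plasma insulin:
#' \describe{
#'   \item{HOMA-IR}{\eqn{G_0 I_0 / 22.5} — homeostasis model of insulin
#'     resistance; higher = more resistant.}
#'   \item{QUICKI}{\eqn{1/(\log_{10} G_0 + \log_{10} I_0)} — quantitative
#'     insulin sensitivity check index; higher = more sensitive. Base-10
#'     logarithms, the convention of the index's originating literature.}
#'   \item{FIRI}{\eqn{G_0 I_0 / 25} — fasting insulin resistance index, a
#'     fixed rescaling of HOMA-IR.}
#' }
#'
#' Units: glucose in mmol/L, insulin in µU/mL — the 22.5 (and 25) denominators
#' presume these units and no conversion is attempted. All three indices are
#' strictly monotone functions of the product \eqn{G_0 I_0}, hence strictly
#' monotone functions of *each other*; see [transform_index()].
#'
#' @param glucose fasting plasma glucose, mmol/L; strictly positive.
#' @param insulin fasting plasma insulin, µU/mL; strictly positive.
#' @return numeric vector of index values.
#' @examples
#' homa_ir(5.0, 9.0)   # 2.0
#' quicki(10, 10)      # 0.5
#' firi(5, 10)         # 2.0
#' @seealso [transform_index()], [compute_indices()]
#' @export
homa_ir <- function(glucose, insulin) {
  check_positive(glucose, "glucose")
  check_positive(insulin, "insulin")
  glucose * insulin / 22.5
}

#' @rdname homa_ir
#' @export
quicki <- function(glucose, insulin) {
  check_positive(glucose, "glucose")
  check_positive(insulin, "insulin")
  denom <- log10(glucose) + log10(insulin)
  if (any(denom == 0)) {
    stop("degenerate input: log10(glucose) + log10(insulin) = 0 ",
         "(glucose * insulin = 1), QUICKI undefined", call. = FALSE)
  }
  1 / denom
}

#' @rdname homa_ir
#' @export
firi <- function(glucose, insulin) {
  check_positive(glucose, "glucose")
  check_positive(insulin, "insulin")
  glucose * insulin / 25
}

# ---- OGTT-based and extended indices ----------------------------------------

#' OGTT-based and extended surrogate indices
#'
#' Indices requiring measurements beyond the fasting sample.
#'
#' `matsuda()` is the composite whole-body sensitivity index
#' \eqn{10000 / \sqrt{G_0 I_0 \bar G \bar I}} with fasting and OGTT-mean
#' glucose/insulin; documented for glucose in mg/dL and insulin in µU/mL.
#'
#' `stumvoll()` is the demographic-free Stumvoll formula
#' \eqn{18.3 - 0.271\,\mathrm{BMI} - 0.0052\,I_{120} - 0.27\,G_{90}};
#' documented for insulin at 120 min in pmol/L and glucose at 90 min in
#' mmol/L. Unlike the other indices it can be negative.
#'
#' `revised_quicki()` extends QUICKI with fasting non-esterified fatty acids:
#' \eqn{1/(\log_{10} G_0 + \log_{10} I_0 + \log_{10} \mathrm{NEFA})}.
#'
#' `fasting_ratio()` is the fasting insulin/glucose ratio (resistance-up) or
#' its reciprocal (sensitivity-up).
#'
#' Missing measurements are an error, never imputed: an index computed on
#' imputed inputs would no longer be the index.
#'
#' @param glucose,insulin fasting glucose and insulin, strictly positive.
#' @param glucose_mean,insulin_mean mean glucose and insulin during the OGTT.
#' @param bmi body mass index, kg/m².
#' @param insulin_120 insulin 120 min after the glucose load, pmol/L.
#' @param glucose_90 glucose 90 min after the glucose load, mmol/L.
#' @param nefa fasting non-esterified fatty acids, mmol/L.
#' @param direction which fasting ratio to form.
#' @return numeric vector of index values.
#' @examples
#' matsuda(100, 10, 100, 10)     # 10
#' stumvoll(25, 400, 5)          # 8.095
#' revised_quicki(10, 10, 10)    # 1/3
#' fasting_ratio(5, 10, "insulin_over_glucose")  # 2
#' @export
matsuda <- function(glucose, insulin, glucose_mean, insulin_mean) {
  if (missing(glucose_mean) || missing(insulin_mean) ||
      is.null(glucose_mean) || is.null(insulin_mean) ||
      anyNA(glucose_mean) || anyNA(insulin_mean)) {
    stop("missing field: matsuda requires OGTT mean glucose and insulin",
         call. = FALSE)
  }
  check_positive(glucose, "glucose")
  check_positive(insulin, "insulin")
  check_positive(glucose_mean, "glucose_mean")
  check_positive(insulin_mean, "insulin_mean")
  10000 / sqrt(glucose * insulin * glucose_mean * insulin_mean)
}

#' @rdname matsuda
#' @export
stumvoll <- function(bmi, insulin_120, glucose_90) {
  if (missing(bmi) || missing(insulin_120) || missing(glucose_90) ||
      is.null(bmi) || is.null(insulin_120) || is.null(glucose_90) ||
      anyNA(bmi) || anyNA(insulin_120) || anyNA(glucose_90)) {
    stop("missing field: stumvoll requires bmi, insulin_120 and glucose_90",
         call. = FALSE)
  }
  check_finite(bmi, "bmi")
  check_finite(insulin_120, "insulin_120")
  check_finite(glucose_90, "glucose_90")
  18.3 - 0.271 * bmi - 0.0052 * insulin_120 - 0.27 * glucose_90
}

#' @rdname matsuda
#' @export
revised_quicki <- function(glucose, insulin, nefa) {
  if (missing(nefa) || is.null(nefa) || anyNA(nefa)) {
    stop("missing field: revised_quicki requires nefa", call. = FALSE)
  }
  check_positive(glucose, "glucose")
  check_positive(insulin, "insulin")
  check_positive(nefa, "nefa")
  denom <- log10(glucose) + log10(insulin) + log10(nefa)
  if (any(denom == 0)) {
    stop("degenerate input: log10 denominator of revised QUICKI is zero",
         call. = FALSE)
  }
  1 / denom
}

#' @rdname matsuda
#' @export
fasting_ratio <- function(glucose, insulin,
                          direction = c("insulin_over_glucose",
                                        "glucose_over_insulin")) {
  direction <- match.arg(direction)
  check_positive(glucose, "glucose")
  check_positive(insulin, "insulin")
  if (direction == "insulin_over_glucose") insulin / glucose
  else glucose / insulin
}

# ---- exact transformations --------------------------------------------------

#' Exact transformations between HOMA-IR, QUICKI and FIRI
#'
#' HOMA-IR, QUICKI and FIRI all depend on the fasting sample only through the
#' product \eqn{G_0 I_0}, so each determines the other two exactly:
#' \deqn{\mathrm{HOMA\mbox{-}IR} = \mathrm{FIRI} \cdot 25/22.5, \qquad
#'       \mathrm{HOMA\mbox{-}IR} = 10^{1/\mathrm{QUICKI}}/22.5,}
#' \deqn{\mathrm{QUICKI} = 1/(\log_{10}\mathrm{HOMA\mbox{-}IR} +
#'       \log_{10} 22.5).}
#' The base-10 exponential matches the base-10 logarithm used by [quicki()].
#' Transformation to an index's own kind is the identity, and every round
#' trip is exact up to floating point. Because each map is strictly monotone,
#' the three indices always carry the same ranks (QUICKI with reversed
#' order), which is what makes all rank-based analyses agree across them.
#'
#' @param value numeric vector of index values of kind `from`.
#' @param from,to one of `"homa_ir"`, `"quicki"`, `"firi"`.
#' @return numeric vector of values of kind `to`.
#' @examples
#' transform_index(2.25, "firi", "homa_ir")               # 2.5
#' transform_index(quicki(5, 9), "quicki", "homa_ir")     # == homa_ir(5, 9)
#' @export
transform_index <- function(value, from, to) {
  fasting3 <- c("homa_ir", "quicki", "firi")
  if (!is.character(from) || length(from) != 1L || !(from %in% fasting3) ||
      !is.character(to) || length(to) != 1L || !(to %in% fasting3)) {
    stop("unsupported transform: 'from' and 'to' must each be one of ",
         paste(fasting3, collapse = ", "), call. = FALSE)
  }
  check_finite(value, "value")
  if (from == to) return(value)
  # route everything through HOMA-IR
  h <- switch(from,
    homa_ir = value,
    firi    = value * 25 / 22.5,
    quicki  = {
      if (any(value == 0)) {
        stop("degenerate input: QUICKI value 0 cannot be inverted",
             call. = FALSE)
      }
      10^(1 / value) / 22.5
    })
  switch(to,
    homa_ir = h,
    firi    = h * 22.5 / 25,
    quicki  = {
      denom <- log10(h) + log10(22.5)
      if (any(denom == 0)) {
        stop("degenerate input: HOMA-IR * 22.5 = 1, QUICKI undefined",
             call. = FALSE)
      }
      1 / denom
    })
}

# ---- batch computation ------------------------------------------------------

#' Compute a requested set of indices from one subject record
#'
#' A record is a named list with fasting fields `glucose_fasting` and
#' `insulin_fasting` and, optionally, `glucose_mean_ogtt`, `insulin_mean_ogtt`,
#' `glucose_90min`, `insulin_120min`, `bmi`, `nefa`. Each requested kind is
#' computed from the fields it needs; kinds whose required fields are absent
#' are reported as explicit per-kind failures (an `error` message and `NA`
#' value), never silently dropped and never imputed.
#'
#' @param record named list (or one-row data frame) of subject measurements.
#' @param kinds character vector of kinds to compute; defaults to all eight.
#'   Results are returned in the canonical `index_kinds()` order.
#' @return data frame with columns `kind`, `value`, `orientation`, `error`
#'   (`NA` when the computation succeeded).
#' @examples
#' rec <- list(glucose_fasting = 5, insulin_fasting = 9)
#' compute_indices(rec, c("homa_ir", "quicki", "firi"))
#' @export
compute_indices <- function(record, kinds = index_kinds()) {
  if (length(kinds) == 0L) {
    stop("invalid input: 'kinds' must name at least one index", call. = FALSE)
  }
  kinds <- match.arg(kinds, index_kinds(), several.ok = TRUE)
  kinds <- index_kinds()[index_kinds() %in% kinds]  # stable canonical order
  record <- as.list(record)
  g <- record$glucose_fasting
  i <- record$insulin_fasting
  one <- function(kind) {
    tryCatch({
      v <- switch(kind,
        homa_ir = homa_ir(g, i),
        quicki = quicki(g, i),
        firi = firi(g, i),
        matsuda = matsuda(g, i, record$glucose_mean_ogtt,
                          record$insulin_mean_ogtt),
        stumvoll = stumvoll(record$bmi, record$insulin_120min,
                            record$glucose_90min),
        revised_quicki = revised_quicki(g, i, record$nefa),
        insulin_glucose_ratio = fasting_ratio(g, i, "insulin_over_glucose"),
        glucose_insulin_ratio = fasting_ratio(g, i, "glucose_over_insulin"))
      list(value = v, error = NA_character_)
    }, error = function(e) list(value = NA_real_, error = conditionMessage(e)))
  }
  res <- lapply(kinds, one)
  data.frame(
    kind = kinds,
    value = vapply(res, function(r) r$value[1L], numeric(1)),
    orientation = index_orientation(kinds),
    error = vapply(res, function(r) r$error, character(1)),
    stringsAsFactors = FALSE
  )
}
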