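# Display names of the four experimental conditions -> case-table fields.
.condition_fields <- c(rep = "rep", CNTtype = "cnt_type",
                       FuncType = "func_type", Solvent = "solvent")

.inv_cols <- function(k_max = 5L) {
  c(paste0("Tr", 0:k_max), paste0("Tre", 0:k_max))
}

#' Expected oxygen flux per experimental-condition group
#'
#' The expected value of the measured flux J_m(O2) for a case is the mean flux
#' over all cases sharing its combination of experimental conditions
#' (averaged over time). The default grouping is the full four-condition
#' combination (rep, CNTtype, FuncType, Solvent); an empty grouping gives the
#' global mean.
#'
#' @param records case table as returned by [read_case_table()].
#' @param grouping character vector of condition display names among
#'   `c("rep", "CNTtype", "FuncType", "Solvent")`; may be empty.
#' @return Numeric vector of per-case expected flux (pmol/s), with the table
#'   of group means attached as attribute `"means"`.
#' @export
expected_flux <- function(records, grouping = names(.condition_fields)) {
  if (nrow(records) == 0L) stop("empty record list")
  bad <- setdiff(grouping, names(.condition_fields))
  if (length(bad) > 0L) stop("unknown condition(s): ", paste(bad, collapse = ", "))
  if (length(grouping) == 0L) {
    out <- rep(mean(records$flux), nrow(records))
    attr(out, "means") <- data.frame(Jm_expected = mean(records$flux))
    return(out)
  }
  fields <- .condition_fields[grouping]
  key <- interaction(records[fields], drop = TRUE, sep = "|")
  mu <- tapply(records$flux, key, mean)
  out <- as.numeric(mu[as.character(key)])
  means <- data.frame(do.call(rbind, strsplit(names(mu), "|", fixed = TRUE)),
                      Jm_expected = as.numeric(mu))
  names(means)[seq_along(fields)] <- names(fields)
  attr(out, "means") <- means
  out
}

.case_invariants <- function(records, invariants, k_max = 5L,
                             control = c("zero", "drop")) {
  control <- match.arg(control)
  cols <- .inv_cols(k_max)
  if (!all(cols %in% names(invariants))) {
    stop("invariant table must have columns ", paste(cols, collapse = ", "))
  }
  ids <- as.character(invariants$cnt_id)
  need <- unique(records$cnt_id)
  unmatched <- setdiff(need, c(ids, "0"))
  if (length(unmatched) > 0L) {
    stop("no trace invariants for cnt_id(s): ", paste(unmatched, collapse = ", "))
  }
  M <- matrix(0, nrow(records), length(cols), dimnames = list(NULL, cols))
  hit <- match(records$cnt_id, ids)
  known <- !is.na(hit)
  M[known, ] <- as.matrix(invariants[hit[known], cols])
  if (control == "drop" && any(!known)) {
    attr(M, "drop_rows") <- which(!known)
  }
  # control cases ("0") keep all-zero invariants under the default policy
  M
}

#' Moving-average (perturbation-theory) deviation operators
#'
#' For one experimental condition c, the MA operator of a case is
#' `dTr_k(c) = Tr_k - <Tr_k(c)>`: the deviation of its trace invariant from
#' the mean invariant over all cases sharing the case's level of that
#' condition (and likewise `dTre_k(c)` for the embedded matrix). Control
#' cases (cnt_id `"0"`) carry all-zero invariants so their deviations are
#' defined. `average_over = "cnts"` computes the reference means over distinct
#' CNT spectra instead of over (time-expanded) cases.
#'
#' @param invariants data.frame from [invariant_table()] (one row per CNT).
#' @param records case table.
#' @param condition one of `"rep"`, `"CNTtype"`, `"FuncType"`, `"Solvent"`.
#' @param k_max largest moment order present (default 5).
#' @param average_over `"cases"` (default) or `"cnts"`.
#' @return data.frame with columns `dTr<k>_<condition>` and
#'   `dTre<k>_<condition>`, one row per case.
#' @export
ma_operators <- function(invariants, records, condition, k_max = 5L,
                         average_over = c("cases", "cnts")) {
  average_over <- match.arg(average_over)
  if (!condition %in% names(.condition_fields)) {
    stop("unknown condition '", condition, "'; expected one of ",
         paste(names(.condition_fields), collapse = ", "))
  }
  M <- .case_invariants(records, invariants, k_max)
  level <- records[[.condition_fields[[condition]]]]
  if (average_over == "cases") {
    centers <- apply(M, 2L, function(col) tapply(col, level, mean))
  } else {
    first <- !duplicated(paste(records$cnt_id, level))
    centers <- apply(M[first, , drop = FALSE], 2L,
                     function(col) tapply(col, level[first], mean))
  }
  if (is.null(dim(centers))) centers <- matrix(centers, nrow = 1,
                                               dimnames = list(unique(level), colnames(M)))
  delta <- M - centers[as.character(level), , drop = FALSE]
  out <- as.data.frame(delta)
  names(out) <- paste0("d", colnames(M), "_", condition)
  out
}

#' Column names of the final eight-feature subset
#'
#' The named subset keeps the expected flux, the assay time and six MA
#' operators — one or two per experimental condition — mirroring the feature
#' set that survives the correlation filter on the full study data.
#'
#' @return Character vector of eight column names.
#' @export
paper8_columns <- function() {
  c("Jm_expected", "t",
    "dTr0_rep", "dTre3_rep", "dTre0_CNTtype", "dTre4_FuncType",
    "dTre0_Solvent", "dTre5_Solvent")
}

#' Assemble the PTML design matrix
#'
#' Builds the full feature table: expected flux `Jm_expected`, time `t`, and
#' the MA deviation columns `dTr<k>_<condition>` / `dTre<k>_<condition>` for
#' k = 0..5 and each of the four conditions (2 + 2*6*4 = 50 feature columns),
#' plus the measured flux as the target column `flux`. Rows are sorted by
#' (cnt_id, rep, solvent, cnt_type, func_type, time) so the output does not
#' depend on the input row order.
#'
#' @param records case table.
#' @param invariants data.frame from [invariant_table()].
#' @param grouping condition names used for the expected flux (default: all
#'   four).
#' @param subset `"full"` (default) or `"paper8"` (the eight-column final
#'   subset of [paper8_columns()]); alternatively a character vector of
#'   feature-column names to keep.
#' @param k_max largest moment order (default 5).
#' @param average_over passed to [ma_operators()].
#' @param control `"zero"` (default: control cases carry zero invariants) or
#'   `"drop"` (control cases are removed).
#' @return data.frame of features plus the target column `flux`.
#' @export
assemble_feature_table <- function(records, invariants,
                                   grouping = names(.condition_fields),
                                   subset = "full", k_max = 5L,
                                   average_over = c("cases", "cnts"),
                                   control = c("zero", "drop")) {
  if (nrow(records) == 0L) stop("empty record list")
  control <- match.arg(control)
  average_over <- match.arg(average_over)
  ord <- do.call(order, records[c("cnt_id", "rep", "solvent", "cnt_type",
                                  "func_type", "time")])
  records <- records[ord, , drop = FALSE]
  if (control == "drop") {
    records <- records[records$cnt_id != "0", , drop = FALSE]
    if (nrow(records) == 0L) stop("no non-control records")
  }
  ma <- lapply(names(.condition_fields), function(cond) {
    ma_operators(invariants, records, cond, k_max = k_max,
                 average_over = average_over)
  })
  out <- cbind(
    data.frame(Jm_expected = as.numeric(expected_flux(records, grouping)),
               t = records$time),
    do.call(cbind, ma),
    data.frame(flux = records$flux)
  )
  rownames(out) <- NULL
  if (identical(subset, "paper8")) subset <- paper8_columns()
  if (!identical(subset, "full")) {
    missing <- setdiff(subset, names(out))
    if (length(missing) > 0L) {
      stop("unknown feature column(s): ", paste(missing, collapse = ", "))
    }
    out <- out[c(subset, "flux")]
  }
  stopifnot(!anyNA(out))
  out
}

#' PTML linear-model coefficients
#'
#' Container for the coefficients of the linear PTML model
#' `Jm_pred = a0 + a1 * Jm_expected + a2 * f(t) + sum_k b_k dTr_k(c_j)
#'  + sum_k c_k dTre_k(c_j)`.
#' The MA terms are held as a single named vector `beta` over feature-table
#' column names (e.g. `c(dTr2_Solvent = 0.05)`), which covers any mix of
#' plain/embedded moments and conditions. `f_t` is the time transform, the
#' identity by default (time itself is the input feature).
#'
#' @param a0,a1,a2 intercept, expected-flux and time coefficients.
#' @param beta named numeric vector of MA-operator coefficients.
#' @param f_t monotone transform applied to `t` (default `identity`).
#' @return Object of class `ptml_coefficients`.
#' @export
ptml_coefficients <- function(a0 = 0, a1 = 0, a2 = 0, beta = numeric(0),
                              f_t = identity) {
  stopifnot(is.finite(a0), is.finite(a1), is.finite(a2),
            is.numeric(beta), all(is.finite(beta)), is.function(f_t))
  if (length(beta) > 0L && is.null(names(beta))) {
    stop("beta must be named by feature-table column")
  }
  structure(list(a0 = a0, a1 = a1, a2 = a2, beta = beta, f_t = f_t),
            class = "ptml_coefficients")
}

#' @export
print.ptml_coefficients <- function(x, ...) {
  cat(sprintf("PTML coefficients: a0 = %g, a1 = %g, a2 = %g\n", x$a0, x$a1, x$a2))
  if (length(x$beta) > 0L) {
    cat("MA terms:\n")
    print(x$beta)
  }
  invisible(x)
}

#' Predict flux with a linear PTML model
#'
#' Evaluates the linear combination of [ptml_coefficients()] on rows of a
#' feature table.
#'
#' @param coeffs a [ptml_coefficients()] object.
#' @param features feature table (data.frame) holding `Jm_expected`, `t` and
#'   every column named in `coeffs$beta`.
#' @return Numeric vector of predicted flux (pmol/s), one per row.
#' @examples
#' row <- data.frame(Jm_expected = 12, t = 100, dTr2_Solvent = -3)
#' cf <- ptml_coefficients(a0 = 1, a1 = 0.5, a2 = 0.01,
#'                         beta = c(dTr2_Solvent = 2))
#' predict_linear_ptml(cf, row)  # 2
#' @export
predict_linear_ptml <- function(coeffs, features) {
  stopifnot(inherits(coeffs, "ptml_coefficients"))
  need <- c("Jm_expected", "t", names(coeffs$beta))
  missing <- setdiff(need, names(features))
  if (length(missing) > 0L) {
    stop("feature table is missing column(s): ", paste(missing, collapse = ", "))
  }
  out <- coeffs$a0 + coeffs$a1 * features$Jm_expected + coeffs$a2 * coeffs$f_t(features$t)
  for (nm in names(coeffs$beta)) {
    out <- out + coeffs$beta[[nm]] * features[[nm]]
  }
  out
}
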