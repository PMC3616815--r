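# quantify: standard-curve method, efficiency, normalization, expression calls

#' Amplification efficiency from a standard-curve slope
#'
#' `E = 10^(-1/slope) - 1`; an `E` of 1 means perfect doubling each cycle.
#' The inverse is `slope = -1 / log10(1 + E)`.
#'
#' @param slope Ct-per-log10-input slope (negative for a valid curve).
#' @return efficiency as a fraction.
#' @export
#' @examples
#' efficiency_from_slope(-3.3219)  # ~1.00
efficiency_from_slope <- function(slope) {
  10^(-1 / slope) - 1
}

#' @rdname efficiency_from_slope
#' @param efficiency amplification efficiency as a fraction.
#' @export
slope_from_efficiency <- function(efficiency) {
  -1 / log10(1 + efficiency)
}

#' Fit a standard curve
#'
#' Ordinary least squares of Ct on log10(input quantity) over a dilution
#' series.  Quantities are relative (dilution step 0 = 1.0); absolute copy
#' numbers are not needed for arbitrary-unit output.
#'
#' @param data a data frame of standard wells.
#' @param quantity column of input quantities (relative).
#' @param ct column of Ct values; censored standards are an error.
#' @return an object of class `standard_curve`: slope, intercept, `r2`,
#'   `efficiency`, `n_points`, `valid`, and the underlying `lm` fit.
#'   [tidy()], [glance()] and [autoplot()] methods are provided.
#' @export
#' @examples
#' std <- tibble::tibble(q = 10^-(0:5), ct = 20 - log10(10^-(0:5)) / log10(2))
#' glance(fit_standard_curve(std, q, ct))
fit_standard_curve <- function(data, quantity, ct) {
  q <- rlang::eval_tidy(rlang::enquo(quantity), data)
  y <- rlang::eval_tidy(rlang::enquo(ct), data)
  if ("censored" %in% names(data) && any(data$censored)) {
    abort("censored Ct values in standards", class = "isoprime_value_error")
  }
  if (anyNA(q) || anyNA(y)) abort("NA in standard-curve inputs", class = "isoprime_value_error")
  if (length(unique(q)) < 3L) abort("need >= 3 distinct dilution levels",
                                    class = "isoprime_value_error")
  x <- log10(q)
  fit <- lm(y ~ x, data = data.frame(x = x, y = y))
  slope <- unname(coef(fit)[2L])
  intercept <- unname(coef(fit)[1L])
  # summary.lm warns on exact fits; r-squared itself is well-defined there
  r2 <- suppressWarnings(summary(fit)$r.squared)
  valid <- slope < 0
  if (!valid) warn("standard-curve slope is non-negative: invalid curve")
  structure(list(slope = slope, intercept = intercept, r2 = r2,
                 efficiency = if (valid) efficiency_from_slope(slope) else NA_real_,
                 n_points = length(y), valid = valid, fit = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> slope = %.4f, intercept = %.3f, r2 = %.4f, E = %s, n = %d%s\n",
              x$slope, x$intercept, x$r2,
              ifelse(is.na(x$efficiency), "NA", sprintf("%.3f", x$efficiency)),
              x$n_points, if (x$valid) "" else " [invalid]"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.standard_curve <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = c("intercept", "log10_quantity"),
         estimate = unname(s[, 1]), std.error = unname(s[, 2]),
         statistic = unname(s[, 3]), p.value = unname(s[, 4]))
}

#' @exportS3Method generics::glance
glance.standard_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r2 = x$r2,
         efficiency = x$efficiency, n_points = x$n_points, valid = x$valid)
}

#' Quantity from Ct via a standard curve
#'
#' `quantity = 10^((ct - intercept) / slope)`.  Censored wells (no signal)
#' yield `NA`, the censored-quantity marker.
#'
#' @param ct numeric Ct values.
#' @param curve a [fit_standard_curve()] object.
#' @param censored optional logical vector marking censored wells.
#' @return relative quantities on the standard's scale.
#' @export
quantity_from_ct <- function(ct, curve, censored = NULL) {
  if (!inherits(curve, "standard_curve") || !curve$valid) {
    abort("need a valid standard curve", class = "isoprime_value_error")
  }
  q <- 10^((ct - curve$intercept) / curve$slope)
  if (!is.null(censored)) q[censored] <- NA_real_
  q
}

#' Normalize a target quantity to the reference gene
#'
#' Arbitrary units: `A.U. = q_target / q_reference`.
#'
#' @param q_target,q_reference relative quantities from [quantity_from_ct()].
#' @return A.U. values.
#' @export
normalize_expression <- function(q_target, q_reference) {
  if (any(q_reference <= 0, na.rm = TRUE)) {
    abort("reference quantity must be positive", class = "isoprime_value_error")
  }
  q_target / q_reference
}

#' dCt-slope check for quantification-method selection
#'
#' Regresses `dCt = Ct_target - Ct_reference` on log10 input over a dilution
#' series.  When `|slope| <= threshold` (default 0.1) target and reference
#' amplify with indistinguishable efficiencies and the comparative ddCt
#' method is permissible; otherwise the standard-curve method is required.
#'
#' @param data a data frame of paired standard wells.
#' @param quantity input-quantity column.
#' @param ct_target,ct_reference Ct columns for target and reference.
#' @param threshold the permissible-slope bound (default 0.1).
#' @return a one-row tibble: `slope`, `threshold`, `method`
#'   (`"ddct_permissible"` or `"standard_curve_required"`).
#' @export
relative_efficiency_slope <- function(data, quantity, ct_target, ct_reference,
                                      threshold = 0.1) {
  q <- rlang::eval_tidy(rlang::enquo(quantity), data)
  a <- rlang::eval_tidy(rlang::enquo(ct_target), data)
  b <- rlang::eval_tidy(rlang::enquo(ct_reference), data)
  fit <- lm(d ~ x, data = data.frame(x = log10(q), d = a - b))
  slope <- unname(coef(fit)[2L])
  tibble(slope = slope, threshold = threshold,
         method = ddct_method_check(slope, threshold))
}

#' @rdname relative_efficiency_slope
#' @param slope one or more dCt slopes to classify directly.
#' @export
ddct_method_check <- function(slope, threshold = 0.1) {
  ifelse(abs(slope) <= threshold, "ddct_permissible", "standard_curve_required")
}

#' Expression call for one assay in one group
#'
#' A gene counts as expressed when at least one biological replicate has all
#' technical replicates detected (Ct below the censoring cycle) and its
#' median Ct at least `guard` cycles below any no-template-control signal
#' (censored NTCs count as signal at `max_cycle`).
#'
#' @param ct technical-replicate Ct values of the unknown wells.
#' @param sample_id biological-replicate identifier per well.
#' @param censored logical, censoring flags per well.
#' @param ntc_ct NTC Ct values (censored NTCs at `max_cycle`).
#' @param max_cycle censoring cycle (default 40).
#' @param guard required clearance below the NTC signal in cycles (default 3).
#' @return a logical scalar.
#' @export
call_expressed <- function(ct, sample_id, censored = rep(FALSE, length(ct)),
                           ntc_ct = numeric(0), max_cycle = 40, guard = 3) {
  ntc_floor <- if (length(ntc_ct)) min(ntc_ct) else max_cycle
  any(vapply(split(seq_along(ct), sample_id), function(idx) {
    all(!censored[idx] & ct[idx] < max_cycle) &&
      median(ct[idx]) <= ntc_floor - guard
  }, logical(1)))
}

#' Rank candidate reference genes by Ct stability
#'
#' Candidates are ranked by the standard deviation of their mean Ct across
#' sample groups (tissue x cultivar by default), ascending: a good reference
#' gene has the same Ct everywhere.
#'
#' @param data a Ct table of candidate-reference wells.
#' @param group_vars grouping columns defining the conditions (default
#'   `c("tissue", "cultivar")`).
#' @return a tibble `assay_id`, `sd_ct`, `rank`, ordered by rank.
#' @export
reference_stability <- function(data, group_vars = c("tissue", "cultivar")) {
  data |>
    group_by(across(dplyr::all_of(c("assay_id", group_vars)))) |>
    summarise(mean_ct = mean(.data$ct), .groups = "drop") |>
    group_by(.data$assay_id) |>
    summarise(sd_ct = sd(.data$mean_ct), .groups = "drop") |>
    arrange(.data$sd_ct) |>
    mutate(rank = row_number())
}

#' Summarise replicate expression values
#'
#' Mean and standard error of the mean over biological replicates.
#'
#' @param data a data frame of per-replicate A.U. values.
#' @param au the A.U. column.
#' @param group_vars grouping columns (default gene/tissue/cultivar-style).
#' @return a tibble with `au_mean`, `au_sem`, `n` per group.
#' @export
summarize_expression <- function(data, au, group_vars = c("assay_id", "tissue", "cultivar")) {
  data |>
    group_by(across(dplyr::all_of(group_vars))) |>
    summarise(au_mean = mean({{ au }}, na.rm = TRUE),
              au_sem = sd({{ au }}, na.rm = TRUE) / sqrt(sum(!is.na({{ au }}))),
              n = sum(!is.na({{ au }})),
              .groups = "drop")
}

#' Fixed-effects ANOVA on expression values
#'
#' Standard sum-of-squares decomposition (additive fixed-effects model) of
#' expression over the given factors, at the conventional 0.05 level.
#'
#' @param data a data frame of expression values.
#' @param response name of the response column (default `"au"`).
#' @param factors character vector of factor columns.
#' @return a tidy ANOVA table: `term`, `df`, `sumsq`, `meansq`, `statistic`,
#'   `p.value`.
#' @export
expression_anova <- function(data, response = "au",
                             factors = c("gene", "tissue", "cultivar")) {
  factors <- intersect(factors, names(data))
  if (length(factors) == 0L) abort("no factor columns found", class = "isoprime_schema_error")
  df <- data
  for (f in factors) df[[f]] <- factor(df[[f]])
  fml <- stats::as.formula(paste(response, "~", paste(factors, collapse = " + ")))
  tab <- anova(lm(fml, data = df))
  tibble(term = rownames(tab), df = tab$Df, sumsq = tab$`Sum Sq`,
         meansq = tab$`Mean Sq`, statistic = tab$`F value`, p.value = tab$`Pr(>F)`)
}

#' Standard-curve-method quantification of a full Ct table
#'
#' The complete workflow of a plate (or set of plates) laid out with
#' per-assay dilution standards, unknown wells in technical replicates and
#' no-template controls:
#'
#' 1. fit a standard curve per assay from the `standard` wells
#'    (dilution step `k` = relative input `10^-k`);
#' 2. check the dCt-slope rule of each target assay against the reference;
#' 3. average technical replicates on the Ct scale per biological sample,
#'    transform to quantities through each assay's own curve (this is what
#'    neutralises efficiency differences between assays);
#' 4. normalize to the reference assay within each sample (A.U.);
#' 5. summarise over biological replicates (mean, SEM) and call expression
#'    against the NTCs.
#'
#' Groups that fail the expression call report `au_mean = 0` with a
#' censoring note.
#'
#' @param ct_table a Ct tibble (see [read_ct_table()]).  Unknown wells carry
#'   `replicate_type` `"technical"` (or `"biological"`); distinct
#'   `sample_id` values are the biological replicates.
#' @param reference_assay the reference gene's `assay_id` (e.g. actin).
#' @param max_cycle censoring cycle (default 40).
#' @param guard expression-call clearance below NTC, cycles (default 3).
#' @param group_vars condition columns (default tissue, cultivar).
#' @return a tibble per (assay, group): `assay_id`, group columns,
#'   `au_mean`, `au_sem`, `n`, `expressed`, `note`, `curve_slope`,
#'   `efficiency`, `r2`, `dct_slope`, `method_recommendation`.
#' @export
quantify_expression <- function(ct_table, reference_assay, max_cycle = 40,
                                guard = 3, group_vars = c("tissue", "cultivar")) {
  if (!"censored" %in% names(ct_table)) ct_table$censored <- FALSE
  std <- filter(ct_table, .data$replicate_type == "standard")
  assays <- unique(ct_table$assay_id)
  if (!reference_assay %in% assays) {
    abort(paste0("reference assay not in table: ", reference_assay),
          class = "isoprime_value_error")
  }
  no_std <- setdiff(assays, unique(std$assay_id))
  if (length(no_std)) abort(paste0("no standard curve wells for assay: ", no_std[1]),
                            class = "isoprime_value_error")
  curves <- lapply(setNames(assays, assays), function(a) {
    s <- filter(std, .data$assay_id == a)
    fit_standard_curve(mutate(s, q = 10^(-.data$dilution_step)), .data$q, .data$ct)
  })
  # dCt slope vs reference, on per-step mean Ct
  step_means <- std |>
    group_by(.data$assay_id, .data$dilution_step) |>
    summarise(ct = mean(.data$ct), .groups = "drop")
  ref_means <- filter(step_means, .data$assay_id == reference_assay) |>
    select("dilution_step", ct_ref = "ct")
  dct <- step_means |>
    filter(.data$assay_id != reference_assay) |>
    inner_join(ref_means, by = "dilution_step") |>
    group_by(.data$assay_id) |>
    summarise(dct_slope = unname(coef(lm(d ~ x, data = data.frame(
      x = log10(10^(-.data$dilution_step)), d = .data$ct - .data$ct_ref)))[2L]),
      .groups = "drop") |>
    mutate(method_recommendation = ddct_method_check(.data$dct_slope))

  unk <- filter(ct_table, .data$replicate_type %in% c("technical", "biological"))
  ntc <- filter(ct_table, .data$replicate_type == "ntc")
  # technical replicates averaged on the Ct scale
  per_sample <- unk |>
    group_by(across(dplyr::all_of(c("sample_id", group_vars, "assay_id")))) |>
    summarise(mean_ct = mean(.data$ct),
              any_censored = any(.data$censored),
              .groups = "drop")
  per_sample$quantity <- NA_real_
  for (a in assays) {
    sel <- per_sample$assay_id == a & !per_sample$any_censored
    per_sample$quantity[sel] <- quantity_from_ct(per_sample$mean_ct[sel], curves[[a]])
  }
  refq <- per_sample |>
    filter(.data$assay_id == reference_assay) |>
    select(dplyr::all_of(c("sample_id", group_vars)), q_ref = "quantity")
  au_tbl <- per_sample |>
    filter(.data$assay_id != reference_assay) |>
    inner_join(refq, by = c("sample_id", group_vars)) |>
    mutate(au = .data$quantity / .data$q_ref)
  res <- summarize_expression(au_tbl, .data$au,
                              group_vars = c("assay_id", group_vars))
  # expression calls per assay x group
  calls <- unk |>
    filter(.data$assay_id != reference_assay) |>
    group_by(across(dplyr::all_of(c("assay_id", group_vars)))) |>
    summarise(expressed = {
      a <- first(.data$assay_id)
      ntc_a <- ntc$ct[ntc$assay_id == a]
      call_expressed(.data$ct, .data$sample_id, .data$censored,
                     ntc_ct = ntc_a, max_cycle = max_cycle, guard = guard)
    }, .groups = "drop")
  curve_tbl <- map_dfr(setdiff(assays, reference_assay), function(a) {
    g <- glance(curves[[a]])
    tibble(assay_id = a, curve_slope = g$slope, efficiency = g$efficiency, r2 = g$r2)
  })
  out <- res |>
    left_join(calls, by = c("assay_id", group_vars)) |>
    left_join(curve_tbl, by = "assay_id") |>
    left_join(dct, by = "assay_id") |>
    mutate(note = ifelse(.data$expressed, NA_character_, "below detection; A.U. censored to 0"),
           au_mean = ifelse(.data$expressed, .data$au_mean, 0),
           au_sem = ifelse(.data$expressed, .data$au_sem, 0))
  out
}
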