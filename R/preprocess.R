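#' Fit the leakage-safe clinical preprocessor on training rows only
#'
#' Learns, from the training rows alone: per-variable imputation values
#' (mean of observed values for scalar/ordinal variables, mode for binary
#' and categorical ones), integer codes for categorical levels (unseen
#' levels map to an explicit "unknown" code 0), and per-variable min/max
#' for subsequent 0--1 scaling. The nicotine-dependence variable follows a
#' conditional rule: subjects flagged as non-smokers get 0 when the score
#' is absent; smokers with an absent score get the training mean of the
#' observed scores.
#'
#' @param train a `clinical_table` restricted to the training subjects.
#' @return a `preprocess_model`.
#' @export
fit_clinical_preprocessor <- function(train) {
  stopifnot(inherits(train, "clinical_table"))
  if (nrow(train) < 2) stop("need at least 2 training subjects")
  kinds <- attr(train, "kinds")
  smoker_col <- attr(train, "smoker_col")
  nicotine_col <- attr(train, "nicotine_col")

  vars <- vector("list", ncol(train))
  names(vars) <- colnames(train)
  for (j in colnames(train)) {
    kind <- kinds[[j]]
    x <- train[[j]]
    obs <- x[!is.na(x)]
    has_rule <- identical(j, nicotine_col)
    if (length(obs) == 0 && !has_rule)
      stop(sprintf("clinical variable '%s' has no observed training value", j))

    if (kind %in% c("scalar", "ordinal")) {
      impute <- if (length(obs) > 0) mean(as.numeric(obs)) else 0
      levels <- NULL
    } else {
      # only levels actually observed in training exist for the model;
      # anything else is "unknown" at apply time
      lev <- if (is.factor(x)) sort(unique(as.character(obs)))
             else sort(unique(obs))
      counts <- table(factor(obs, levels = lev))
      impute_level <- names(counts)[which.max(counts)]  # ties: first level
      if (kind == "categorical") {
        levels <- as.character(lev)
        impute <- match(impute_level, levels)
      } else {
        levels <- NULL
        impute <- as.numeric(impute_level)
      }
    }
    vars[[j]] <- list(kind = kind, impute = impute, levels = levels)
  }

  model <- structure(list(vars = vars, smoker_col = smoker_col,
                          nicotine_col = nicotine_col,
                          fitted_on = rownames(train), ranges = NULL),
                     class = "preprocess_model")
  # scaling ranges come from the encoded+imputed training rows
  enc <- encode_clinical(model, train)
  model$ranges <- data.frame(min = apply(enc, 2, min),
                             max = apply(enc, 2, max))
  model
}

# impute + integer-code a clinical table with a fitted model (no scaling)
encode_clinical <- function(model, table) {
  n <- nrow(table)
  out <- matrix(NA_real_, n, length(model$vars),
                dimnames = list(rownames(table), names(model$vars)))
  smoker <- if (!is.na(model$smoker_col)) table[[model$smoker_col]] else NULL
  if (!is.null(smoker) && anyNA(smoker)) {
    smoker[is.na(smoker)] <- model$vars[[model$smoker_col]]$impute
  }
  for (j in names(model$vars)) {
    vm <- model$vars[[j]]
    x <- table[[j]]
    if (vm$kind == "categorical") {
      code <- match(as.character(x), vm$levels)
      unseen <- !is.na(as.character(x)) & is.na(code)
      if (any(unseen)) {
        message(sprintf("apply_clinical_preprocessor: %d unseen level(s) in '%s' mapped to the unknown code",
                        sum(unseen), j))
        code[unseen] <- 0
      }
      code[is.na(x)] <- vm$impute
      out[, j] <- code
    } else {
      x <- as.numeric(x)
      if (identical(j, model$nicotine_col) && !is.null(smoker)) {
        x[is.na(x) & smoker == 0] <- 0
      }
      x[is.na(x)] <- vm$impute
      out[, j] <- x
    }
  }
  out
}

#' Apply a fitted clinical preprocessor
#'
#' Imputes missing values with the training-derived values, integer-codes
#' categorical variables (one column per variable), and min-max scales each
#' column with the training min/max so that training rows land in
#' \[0, 1\]. Test values outside the training range are clipped to
#' \[0, 1\]; a degenerate training range (max = min, an information-free
#' column) maps to 0 for all rows.
#'
#' @param model a `preprocess_model` from [fit_clinical_preprocessor()].
#' @param table a `clinical_table` (training or test rows).
#' @return numeric matrix with one column per clinical variable.
#' @export
apply_clinical_preprocessor <- function(model, table) {
  stopifnot(inherits(model, "preprocess_model"))
  if (!identical(colnames(table), names(model$vars)))
    stop("table columns do not match the fitted preprocessor")
  enc <- encode_clinical(model, table)
  rng <- model$ranges[colnames(enc), ]
  span <- rng$max - rng$min
  scaled <- sweep(enc, 2, rng$min)
  scaled <- sweep(scaled, 2, ifelse(span > 0, span, 1), "/")
  scaled[, span <= 0] <- 0
  pmin(pmax(scaled, 0), 1)  # argument order keeps the dimnames
}
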