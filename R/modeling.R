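# Composite fixed-effects formula: five interaction sets, each expanded to
# all component lower-order interactions and main effects by R's formula
# algebra; duplicated terms are deduplicated automatically.
aim_design_formula <- function() {
  sd_aim ~ expectation * number * size * tmf_hand * tmf_head +
    closedeyes * (number + size + expectation) * tmf_head +
    expectation * number * w_hand * w_head +
    closedeyes * (number + size + expectation) * (mean_head + sd_head) +
    number * half
}

pretty_term <- function(labels) {
  map <- c(expectation = "Expectation", closedeyes = "Closedeyes",
           number = "Number(Epoch)", size = "Size(Epoch)", half = "Half",
           tmf_hand = "t_MF(Hand)", tmf_head = "t_MF(Head)",
           w_hand = "W_MF(Hand)", w_head = "W_MF(Head)",
           mean_head = "Mean(Head)", sd_head = "SD(Head)")
  vapply(strsplit(labels, ":", fixed = TRUE), function(parts) {
    known <- parts %in% names(map)
    ord <- order(ifelse(known, match(parts, names(map)), Inf))
    paste(ifelse(known, map[parts], parts)[ord], collapse = " × ")
  }, character(1))
}

#' Interaction design matrix for the aiming-variability model
#'
#' Builds the fixed-effects design for SD(Aim): the union of five
#' interaction sets —
#' Expectation x Number(Epoch) x Size(Epoch) x t_MF(Hand) x t_MF(Head);
#' Closedeyes x (Number + Size + Expectation) x t_MF(Head);
#' Expectation x Number(Epoch) x W_MF(Hand) x W_MF(Head);
#' Closedeyes x (Number + Size + Expectation) x (Mean(Head) + SD(Head));
#' and Number(Epoch) x Half — each expanded to all component lower-order
#' interactions and main effects. All covariates are numeric (epoch size
#' enters as 20/40/80), so every term is a single product column. Columns
#' that are aliased (rank-deficient) on the supplied records are dropped
#' with a warning.
#'
#' @param records Record table from \code{\link{analyze_study}} (flagged
#'   rows and incomplete cases are removed).
#' @param center Center continuous covariates before expansion (default
#'   FALSE, mirroring raw-coefficient reporting).
#' @return List with \code{x} (design matrix, no intercept column),
#'   \code{terms} (syntactic labels), \code{labels} (pretty names),
#'   \code{records} (the rows used), \code{dropped} (aliased terms).
#' @export
build_design <- function(records, center = FALSE) {
  need <- c("sd_aim", "expectation", "number", "size", "tmf_hand",
            "tmf_head", "closedeyes", "w_hand", "w_head", "mean_head",
            "sd_head", "half", "participant")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records are missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.null(records$flagged)) records <- records[!records$flagged, ]
  records <- records[stats::complete.cases(records[, need]), ]
  if (nrow(records) < 2) stop("too few complete records", call. = FALSE)
  if (center) {
    for (v in c("number", "size", "tmf_hand", "tmf_head", "w_hand",
                "w_head", "mean_head", "sd_head"))
      records[[v]] <- records[[v]] - mean(records[[v]])
  }
  tt <- stats::terms(aim_design_formula())
  x <- stats::model.matrix(tt, data = records)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  qrx <- qr(cbind(1, x))
  retained <- sort(qrx$pivot[seq_len(qrx$rank)])
  retained <- retained[retained > 1L] - 1L
  dropped <- setdiff(colnames(x), colnames(x)[retained])
  if (length(dropped))
    warning("dropping aliased terms: ", paste(dropped, collapse = ", "))
  x <- x[, retained, drop = FALSE]
  list(x = x, terms = colnames(x), labels = pretty_term(colnames(x)),
       records = records, dropped = dropped)
}

#' Mixed-effects model of aiming variability
#'
#' Fits the interaction design of \code{\link{build_design}} to SD(Aim)
#' with a participant random intercept, using \code{nlme::lme}. Returns
#' the coefficient table (estimate, SE, p per term), within-sample
#' predictions, and the Pearson correlation between predicted and actual
#' SD(Aim).
#'
#' @param records Record table.
#' @param method \code{"REML"} (default) or \code{"ML"}.
#' @param center Passed to \code{\link{build_design}}.
#' @return Object of class \code{"aim_model"}: list with
#'   \code{coefficients} (data frame: term, label, estimate, se, df, t, p),
#'   \code{predictions}, \code{fit_r}, \code{ranef_sd},
#'   \code{resid_sd}, \code{n_records}, \code{n_participants},
#'   \code{dropped}, \code{design}, and the underlying \code{lme} fit.
#' @export
fit_aim_model <- function(records, method = c("REML", "ML"), center = FALSE) {
  method <- match.arg(method)
  des <- build_design(records, center = center)
  dat <- data.frame(sd_aim = des$records$sd_aim,
                    participant = factor(des$records$participant))
  safe <- paste0("b", seq_along(des$terms))
  for (j in seq_along(safe)) dat[[safe[j]]] <- des$x[, j]
  fixed <- stats::reformulate(safe, response = "sd_aim")
  fit <- tryCatch(
    nlme::lme(fixed, random = ~ 1 | participant, data = dat,
              method = method,
              control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                         msMaxIter = 200, returnObject = TRUE)),
    error = function(e)
      stop("mixed-model fit failed to converge: ", conditionMessage(e),
           call. = FALSE))
  tab <- summary(fit)$tTable
  tab <- tab[rownames(tab) != "(Intercept)", , drop = FALSE]
  coefs <- data.frame(term = des$terms, label = des$labels,
                      estimate = tab[, "Value"], se = tab[, "Std.Error"],
                      df = tab[, "DF"], t = tab[, "t-value"],
                      p = tab[, "p-value"], row.names = NULL)
  pred <- as.numeric(stats::fitted(fit))
  vc <- nlme::VarCorr(fit)
  structure(list(
    coefficients = coefs,
    predictions = pred,
    fit_r = stats::cor(pred, des$records$sd_aim),
    ranef_sd = suppressWarnings(as.numeric(vc["(Intercept)", "StdDev"])),
    resid_sd = suppressWarnings(as.numeric(vc["Residual", "StdDev"])),
    n_records = nrow(des$records),
    n_participants = length(unique(des$records$participant)),
    dropped = des$dropped,
    design = des,
    lme = fit
  ), class = "aim_model")
}

#' @export
print.aim_model <- function(x, ...) {
  cat(sprintf(
    "Mixed-effects model of SD(Aim): %d records, %d participants, %d terms\n",
    x$n_records, x$n_participants, nrow(x$coefficients)))
  cat(sprintf("  predicted-vs-actual r = %.4f\n", x$fit_r))
  sig <- x$coefficients[x$coefficients$p < 0.05, c("label", "estimate", "se", "p")]
  if (nrow(sig)) {
    cat("  significant terms (p < 0.05):\n")
    for (i in seq_len(nrow(sig)))
      cat(sprintf("    %-60s B = %+.3g  SE = %.3g  p = %.3g\n",
                  sig$label[i], sig$estimate[i], sig$se[i], sig$p[i]))
  }
  invisible(x)
}

#' Bootstrap power analysis by participant resampling
#'
#' Resamples participants with replacement \code{n_boot} times, refits the
#' model on each resample (resampled participants get fresh identifiers so
#' duplicates contribute independent random effects), and reports per term
#' the fraction of converged resamples with p below \code{alpha}.
#'
#' @param records Record table.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed RNG seed.
#' @param method Estimation method passed to \code{\link{fit_aim_model}}.
#' @return Data frame: term, label, power, n_eval (resamples where the
#'   term was estimable), with attribute \code{n_failed} (non-converged
#'   resamples, excluded from denominators).
#' @export
bootstrap_power <- function(records, n_boot = 1000, alpha = 0.05,
                            seed = NULL, method = "REML") {
  base <- fit_aim_model(records, method = method)
  terms_all <- base$coefficients$term
  hits <- matrix(0L, length(terms_all), 2L,
                 dimnames = list(terms_all, c("sig", "eval")))
  n_failed <- 0L
  ids <- unique(records$participant)
  for (b in seq_len(n_boot)) {
    take <- with_seed(child_seed(seed, "boot", b),
                      sample(ids, length(ids), replace = TRUE))
    res <- do.call(rbind, lapply(seq_along(take), function(i) {
      r <- records[records$participant == take[i], , drop = FALSE]
      r$participant <- i
      r
    }))
    fit <- tryCatch(
      suppressWarnings(fit_aim_model(res, method = method)),
      error = function(e) NULL)
    if (is.null(fit)) {
      n_failed <- n_failed + 1L
      next
    }
    got <- match(fit$coefficients$term, terms_all)
    ok <- !is.na(got)
    hits[got[ok], "eval"] <- hits[got[ok], "eval"] + 1L
    sig <- fit$coefficients$p[ok] < alpha
    hits[got[ok][sig], "sig"] <- hits[got[ok][sig], "sig"] + 1L
  }
  out <- data.frame(term = terms_all, label = base$coefficients$label,
                    power = ifelse(hits[, "eval"] > 0,
                                   hits[, "sig"] / hits[, "eval"], NA_real_),
                    n_eval = hits[, "eval"], row.names = NULL)
  attr(out, "n_failed") <- n_failed
  out
}

#' Range of nonlinearity-driven model predictions versus observed spread
#'
#' Summarizes how much of the observed epoch-by-epoch spread in SD(Aim)
#' the nonlinearity-driven model terms span: the predicted range is the
#' maximum minus the minimum of the summed predicted contributions, the
#' observed spread is the interquartile range of SD(Aim), and the coverage
#' ratio is their quotient as a percentage.
#'
#' @param predicted Summed nonlinearity-driven predicted contributions
#'   (any vector; only its range is used).
#' @param observed Observed epoch-by-epoch SD(Aim) values; their first and
#'   third quartiles are taken with \code{stats::quantile}.
#' @param observed_quartiles Alternatively, the precomputed
#'   \code{c(Q1, Q3)} of observed SD(Aim).
#' @return List with \code{predicted_range}, \code{observed_iqr},
#'   \code{coverage_pct} (NA with \code{flagged = TRUE} when the IQR is
#'   zero).
#' @examples
#' summarize_effect_range(c(-0.0025, 0.0035),
#'                        observed_quartiles = c(0.0131, 0.0194))
#' @export
summarize_effect_range <- function(predicted, observed = NULL,
                                   observed_quartiles = NULL) {
  if (!length(predicted)) stop("`predicted` is empty", call. = FALSE)
  if (is.null(observed_quartiles)) {
    if (is.null(observed) || !length(observed))
      stop("supply `observed` values or `observed_quartiles`", call. = FALSE)
    observed_quartiles <- unname(stats::quantile(observed, c(0.25, 0.75),
                                                 na.rm = TRUE))
  }
  pr <- max(predicted) - min(predicted)
  iqr <- observed_quartiles[2] - observed_quartiles[1]
  if (iqr <= 0)
    return(list(predicted_range = pr, observed_iqr = iqr,
                coverage_pct = NA_real_, flagged = TRUE))
  list(predicted_range = pr, observed_iqr = iqr,
       coverage_pct = 100 * pr / iqr, flagged = FALSE)
}

#' Summed nonlinearity-driven predicted contributions at t_MF quartiles
#'
#' Evaluates the fitted model's t_MF-involving terms over the analyzed
#' records with both t_MF covariates pinned at their first quartile and,
#' separately, at their third quartile (high-with-high, low-with-low), and
#' sums the corresponding predicted contributions. The range of these
#' contributions is the model-predicted span of SD(Aim) attributable to
#' nonlinearity over the middle 50\% of the nonlinearity estimates.
#'
#' @param fit An \code{\link{aim_model}}.
#' @return List with \code{contributions} (numeric vector over records x
#'   quartile settings), \code{quartiles_hand}, \code{quartiles_head},
#'   and \code{range}.
#' @export
nonlinearity_contributions <- function(fit) {
  stopifnot(inherits(fit, "aim_model"))
  recs <- fit$design$records
  qh <- stats::quantile(recs$tmf_hand, c(0.25, 0.75), na.rm = TRUE)
  qd <- stats::quantile(recs$tmf_head, c(0.25, 0.75), na.rm = TRUE)
  is_tmf <- grepl("tmf_hand|tmf_head", fit$coefficients$term)
  if (!any(is_tmf)) stop("model contains no t_MF terms", call. = FALSE)
  bet <- fit$coefficients$estimate[is_tmf]
  contrib_at <- function(k) {
    r <- recs
    r$tmf_hand <- qh[k]
    r$tmf_head <- qd[k]
    x <- stats::model.matrix(stats::terms(aim_design_formula()), data = r)
    x <- x[, fit$coefficients$term[is_tmf], drop = FALSE]
    drop(x %*% bet)
  }
  contributions <- c(contrib_at(1), contrib_at(2))
  list(contributions = contributions,
       quartiles_hand = qh, quartiles_head = qd,
       range = max(contributions) - min(contributions))
}
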