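#' Fit the variance-components mixed model on index values
#'
#' ANOVA mixed model with similar-exposure group and season as fixed
#' effects and worker as the single random grouping, estimated by
#' restricted maximum likelihood (REML) via `lme4`. The response is
#' the (imputed) daily index, modelled on the log scale by default:
#' index values are strictly positive after imputation and their
#' distribution is heavily right-skewed. The model decomposes the
#' residual variability into a between-worker component (the random
#' intercept variance) and a within-worker component (the residual
#' variance).
#'
#' For comparing models with different fixed effects, `neg2_loglik` is
#' the -2 log-likelihood of the maximum-likelihood refit (REML
#' likelihoods are not comparable across fixed-effect structures).
#'
#' @param data a [study_dataset()] (rows with `in_model` are used; run
#'   [impute_censored()] first) or a model-frame data frame with
#'   columns `person_id`, the fixed factors and the response.
#' @param fixed character vector of fixed-effect factor names (default
#'   `c("seg", "season")`; use `character(0)` for intercept-only).
#' @param log_response model `log(response)` (default `TRUE`).
#' @param response response column (default `"index_model"`, falling
#'   back to `"index"`).
#' @return object of class `varcomp_result`: `fixed_effects`
#'   (coefficient table), `var_between_person`, `var_within_person`,
#'   `within_fraction`, `neg2_loglik`, `n_obs`, `n_persons`, the `fit`
#'   (`lmerMod`) and the settings used.
#' @export
fit_varcomp <- function(data, fixed = c("seg", "season"),
                        log_response = TRUE, response = NULL) {
  from_dataset <- inherits(data, "study_dataset")
  if (from_dataset) {
    d <- data$days
    if (!"in_model" %in% names(d))
      stop("run impute_censored() before fitting; no model frame present")
    d <- d[d$in_model, , drop = FALSE]
    # a short campaign need not span all calendar seasons
    for (f in fixed) if (is.factor(d[[f]])) d[[f]] <- droplevels(d[[f]])
  } else d <- as.data.frame(data)
  if (is.null(response))
    response <- if ("index_model" %in% names(d)) "index_model" else "index"
  stopifnot(response %in% names(d), "person_id" %in% names(d))

  y <- d[[response]]
  if (log_response) {
    if (any(y <= 0))
      stop("log response requires positive index values; impute censored days first")
    y <- log(y)
  }
  d$.y <- y
  d$person_id <- factor(d$person_id)
  for (f in fixed) {
    if (!is.factor(d[[f]])) d[[f]] <- factor(d[[f]])  # declared levels kept
    tab <- table(d[[f]])
    if (any(tab == 0))
      stop("fixed factor '", f, "' has level(s) without data: ",
           paste(names(tab)[tab == 0], collapse = ", "))
  }
  if (nlevels(d$person_id) < 2)
    stop("variance components need at least 2 persons")

  rhs <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  form <- stats::as.formula(paste(".y ~", rhs, "+ (1 | person_id)"))
  fit <- lme4::lmer(form, data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_between <- vc$vcov[vc$grp == "person_id"]
  var_within <- vc$vcov[vc$grp == "Residual"]
  ml <- lme4::refitML(fit)

  co <- summary(fit)$coefficients
  structure(
    list(fixed_effects = data.frame(term = rownames(co),
                                    estimate = co[, "Estimate"],
                                    std_error = co[, "Std. Error"],
                                    row.names = NULL),
         var_between_person = var_between,
         var_within_person = var_within,
         within_fraction = var_within / (var_within + var_between),
         neg2_loglik = as.numeric(-2 * stats::logLik(ml)),
         n_obs = nrow(d), n_persons = nlevels(d$person_id),
         fixed = fixed, log_response = log_response, response = response,
         fit = fit),
    class = "varcomp_result"
  )
}

#' @export
print.varcomp_result <- function(x, ...) {
  cat(sprintf("<varcomp_result> %d obs, %d persons | fixed: %s | %s scale\n",
              x$n_obs, x$n_persons,
              if (length(x$fixed)) paste(x$fixed, collapse = " + ") else "intercept",
              if (x$log_response) "log" else "raw"))
  cat(sprintf("  between-worker var %.4f | within-worker var %.4f (%.0f%% within)\n",
              x$var_between_person, x$var_within_person,
              100 * x$within_fraction))
  cat(sprintf("  -2 logLik (ML) %.2f\n", x$neg2_loglik))
  invisible(x)
}

#' Compare two mixed models by -2 log-likelihood
#'
#' Reports the difference in -2 log-likelihood; a decrease means the
#' better fit. Only models fit to the same response vector (same
#' number of observations, same scale) are comparable.
#'
#' @param r1,r2 `varcomp_result` objects.
#' @param labels length-2 labels for the report.
#' @return list with `delta` (`neg2_loglik(r1) - neg2_loglik(r2)`) and
#'   `better`, the label of the smaller -2 logLik (`"tie"` at exact
#'   equality).
#' @export
compare_models <- function(r1, r2, labels = c("model1", "model2")) {
  stopifnot(inherits(r1, "varcomp_result"), inherits(r2, "varcomp_result"))
  if (r1$n_obs != r2$n_obs)
    stop("models fit to different data (", r1$n_obs, " vs ", r2$n_obs,
         " observations); -2 logLik not comparable")
  if (r1$log_response != r2$log_response)
    stop("models use different response scales; not comparable")
  delta <- r1$neg2_loglik - r2$neg2_loglik
  list(delta = delta,
       better = if (delta == 0) "tie" else labels[(delta < 0) + 1][1],
       neg2_loglik = stats::setNames(c(r1$neg2_loglik, r2$neg2_loglik), labels))
}

#' Predicted cell mean with 95% confidence interval
#'
#' Model-based estimate of the mean index for one combination of fixed
#' factor levels (e.g. a similar-exposure group in one season), as a
#' linear combination of the fixed effects with a Wald-type 95% CI on
#' the model scale. When the model is on the log scale, estimate and
#' CI are back-transformed, giving the asymmetric intervals typical of
#' log-normal exposure data.
#'
#' @param result a `varcomp_result`.
#' @param cell named list/vector of factor levels, e.g.
#'   `list(seg = "water_network", season = "autumn")`.
#' @return one-row data frame: the cell levels, `estimate`, `lower`,
#'   `upper` (response scale).
#' @export
predict_cell_mean <- function(result, cell = list()) {
  stopifnot(inherits(result, "varcomp_result"))
  fit <- result$fit
  fe <- lme4::fixef(fit)
  frame <- stats::model.frame(fit)
  nd <- list()
  for (f in result$fixed) {
    if (is.null(cell[[f]]))
      stop("cell must give a level for fixed factor '", f, "'")
    lev <- levels(frame[[f]])
    if (!cell[[f]] %in% lev)
      stop("level '", cell[[f]], "' of '", f, "' was not seen in the fit")
    nd[[f]] <- factor(cell[[f]], levels = lev)
  }
  nd <- if (length(nd)) as.data.frame(nd) else data.frame(row.names = 1)
  X <- stats::model.matrix(stats::delete.response(stats::terms(fit)), nd)
  # lme4 drops columns from rank-deficient designs; align to the kept ones
  X <- X[, names(fe), drop = FALSE]
  est <- drop(X %*% fe)
  se <- sqrt(drop(X %*% as.matrix(stats::vcov(fit)) %*% t(X)))
  z <- stats::qnorm(0.975)
  out <- data.frame(estimate = est, lower = est - z * se, upper = est + z * se)
  if (result$log_response) out[] <- lapply(out, exp)
  if (length(cell))
    out <- cbind(as.data.frame(lapply(cell, as.character),
                               stringsAsFactors = FALSE),
                 out, row.names = NULL)
  out
}

#' Split positive measurements into two balanced halves
#'
#' Robustness device: the positive measurements with activity data are
#' split at random into two parts, redrawing until each part holds
#' 50% +/- `tol_overall` of the datapoints overall and simultaneously
#' 50% +/- `tol_seg` within every similar-exposure group. The mixed
#' model can then be refit on each half and compared to the full-data
#' fit. Reproducible from the seed; the iteration count is reported.
#'
#' @param data data frame of datapoints with a `seg` column (callers
#'   filter to positive measurements with activity data first), or a
#'   `study_dataset` (rows with `in_model & !censored & has_logbook`
#'   are used when those columns exist).
#' @param seed integer seed (mandatory: the draw is random).
#' @param max_iter maximum redraws before giving up.
#' @param tol_overall overall half-size tolerance (fraction, default
#'   0.025).
#' @param tol_seg per-group half-size tolerance (fraction, default
#'   0.035).
#' @return object of class `split_result`: `part1`/`part2` (integer row
#'   indices), `in_part1` (logical vector), `n_iterations`, `seed`,
#'   `tolerances`.
#' @export
robustness_split <- function(data, seed, max_iter = 10000,
                             tol_overall = 0.025, tol_seg = 0.035) {
  if (inherits(data, "study_dataset")) {
    d <- data$days
    keep <- d$status == "measured" & !d$censored
    if ("has_logbook" %in% names(d)) keep <- keep & d$has_logbook
    d <- d[keep, , drop = FALSE]
  } else d <- as.data.frame(data)
  stopifnot("seg" %in% names(d), is.numeric(seed), length(seed) == 1)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 datapoints to split")

  seg <- factor(d$seg)
  sizes <- table(seg)
  # feasibility: a group of odd size m can at best be split 50% +/- 0.5/m
  infeasible <- names(sizes)[(sizes %% 2 == 1) & (0.5 / as.numeric(sizes) > tol_seg)]
  if (length(infeasible))
    stop("per-group tolerance unsatisfiable for SEG(s): ",
         paste(infeasible, collapse = ", "),
         " (size(s) ", paste(sizes[infeasible], collapse = ", "), ")")

  set.seed(as.integer(seed))
  for (it in seq_len(max_iter)) {
    in1 <- stats::rbinom(n, 1, 0.5) == 1
    if (check_split(in1, seg, tol_overall, tol_seg)) {
      return(structure(
        list(part1 = which(in1), part2 = which(!in1), in_part1 = in1,
             n_iterations = it, seed = as.integer(seed),
             tolerances = c(overall = tol_overall, per_seg = tol_seg)),
        class = "split_result"
      ))
    }
  }
  stop("no admissible split in ", max_iter, " iterations")
}

#' Verify a split against its balance constraints
#'
#' Independent checker for [robustness_split()]: each part must hold
#' 50% +/- `tol_overall` of all datapoints and 50% +/- `tol_seg` of
#' every group.
#'
#' @param in_part1 logical assignment vector.
#' @param seg group factor, same length.
#' @param tol_overall,tol_seg tolerances as fractions.
#' @return `TRUE`/`FALSE`.
#' @export
check_split <- function(in_part1, seg, tol_overall = 0.025,
                        tol_seg = 0.035) {
  n <- length(in_part1)
  if (abs(mean(in_part1) - 0.5) > tol_overall + 1e-12) return(FALSE)
  for (s in levels(factor(seg))) {
    i <- seg == s
    if (abs(mean(in_part1[i]) - 0.5) > tol_seg + 1e-12) return(FALSE)
  }
  TRUE
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> %d | %d datapoints after %d iteration(s), seed %d\n",
              length(x$part1), length(x$part2), x$n_iterations, x$seed))
  invisible(x)
}
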