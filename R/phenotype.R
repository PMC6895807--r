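#' Canonical transform lookup
#'
#' @param trait trait name(s) from the canonical panel ([ems_traits()]).
#' @return transform tag(s): `"identity"`, `"sqrt"` or `"log"`.
#' @export
canonical_transform <- function(trait) {
  tr <- ems_traits()
  tag <- tr$transform[match(trait, tr$trait)]
  if (anyNA(tag)) stop("trait(s) not in canonical panel: ",
                       paste(trait[is.na(tag)], collapse = ", "))
  tag
}

#' Choose a normalizing transform for a trait
#'
#' In `"auto"` mode the candidate transforms (identity always; sqrt when all
#' values are >= 0; log when all values are > 0) are scored by the
#' Shapiro-Wilk W statistic and the maximizer returned. Shapiro-Wilk is
#' limited to n <= 5000; larger vectors are deterministically subsampled.
#' In `"canonical"` mode the paper-panel assignment for `trait` is returned
#' (sqrt: adiponectin, leptin, NEFA; log: insulin, INS-OST, TG, ACTH;
#' identity: glucose, GLU-OST, NH, GH).
#'
#' @param values numeric trait values (>= 20 non-missing required).
#' @param mode `"auto"` or `"canonical"`.
#' @param trait trait name, required for `"canonical"`.
#' @return transform tag.
#' @export
choose_transform <- function(values, mode = c("auto", "canonical"),
                             trait = NULL) {
  mode <- match.arg(mode)
  if (mode == "canonical") {
    if (is.null(trait)) stop("canonical mode requires a trait name")
    return(canonical_transform(trait))
  }
  x <- values[!is.na(values)]
  if (length(x) < 20) stop("need >= 20 non-missing values")
  if (stats::sd(x) == 0) stop("degenerate input: all values identical")
  if (length(x) > 5000) {
    idx <- round(seq(1, length(x), length.out = 5000))
    x <- sort(x)[idx]
  }
  w_of <- function(y) {
    if (stats::sd(y) == 0) return(-Inf)
    as.numeric(stats::shapiro.test(y)$statistic)
  }
  cand <- c(identity = w_of(x))
  if (all(x >= 0)) cand["sqrt"] <- w_of(sqrt(x))
  if (all(x > 0)) cand["log"] <- w_of(log(x))
  names(cand)[which.max(cand)]
}

#' Apply a transform tag
#'
#' @param values numeric vector.
#' @param tag `"identity"`, `"sqrt"` or `"log"`.
#' @return transformed values.
#' @export
apply_transform <- function(values, tag) {
  switch(tag,
         identity = values,
         sqrt = { if (any(values < 0, na.rm = TRUE))
                    stop("sqrt transform requires values >= 0")
                  sqrt(values) },
         log = { if (any(values <= 0, na.rm = TRUE))
                   stop("log transform requires values > 0")
                 log(values) },
         stop("unknown transform tag: ", tag))
}

#' Fit the covariate-adjustment random-intercept model
#'
#' REML fit of `y = intercept + sex + age + (1 | farm)`: sex and age as
#' fixed effects, farm as a random intercept. The fit is delegated to
#' `lme4::lmer`.
#'
#' @param values numeric trait values.
#' @param covariates data.frame with columns `sex` (factor/character),
#'   `age` (numeric) and `farm` (factor/character); no missing values.
#' @return list of class `random_intercept_fit` with `fixed` (named
#'   coefficients), `sigma2_farm`, `sigma2_resid`, `blups` (named farm
#'   effects), `loglik` (REML criterion) and the underlying `model`.
#' @export
fit_random_intercept <- function(values, covariates) {
  stopifnot(all(c("sex", "age", "farm") %in% names(covariates)))
  if (anyNA(values) || anyNA(covariates$sex) || anyNA(covariates$age) ||
      anyNA(covariates$farm)) {
    stop("missing values in trait or covariates; residualization requires complete data")
  }
  if (length(unique(covariates$farm)) < 2) stop("need >= 2 farms")
  dat <- data.frame(y = values,
                    sex = factor(covariates$sex),
                    age = as.numeric(covariates$age),
                    farm = factor(covariates$farm))
  form <- if (nlevels(dat$sex) > 1) y ~ sex + age + (1 | farm)
          else y ~ age + (1 | farm)
  fit <- lme4::lmer(form, data = dat, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  blup <- lme4::ranef(fit)$farm
  structure(list(
    fixed = lme4::fixef(fit),
    sigma2_farm = vc$vcov[vc$grp == "farm"],
    sigma2_resid = vc$vcov[vc$grp == "Residual"],
    blups = stats::setNames(blup[[1]], rownames(blup)),
    loglik = as.numeric(stats::logLik(fit)),
    model = fit
  ), class = "random_intercept_fit")
}

#' Conditional residuals from the adjustment model
#'
#' Returns `y - X beta - Z u`: both the fixed effects (sex, age) and the
#' farm BLUPs are subtracted, so the residuals carry no farm-level signal.
#'
#' @param values trait values used in the fit.
#' @param covariates covariate table used in the fit.
#' @param fit a [fit_random_intercept()] result.
#' @return numeric vector of adjusted trait values.
#' @export
residualize <- function(values, covariates, fit) {
  stopifnot(inherits(fit, "random_intercept_fit"))
  as.numeric(stats::residuals(fit$model))
}

#' Transform and residualize a trait panel
#'
#' For each trait: choose/apply the normalizing transform, fit the
#' random-intercept adjustment model, and return conditional residuals.
#' Binary traits are passed through the same linear adjustment on the
#' observed 0/1 scale (no transform).
#'
#' @param phenotypes data.frame with covariate columns (`sex`, `age`,
#'   `farm`) and one column per trait.
#' @param traits trait panel data.frame (`trait`, `transform`, `type`);
#'   defaults to the canonical panel restricted to columns present.
#' @param transform_mode `"canonical"` (default, reproduces the panel
#'   assignments) or `"auto"` (data-driven Shapiro-Wilk selection).
#' @return data.frame: `sample` plus one adjusted column per trait, with a
#'   `transforms` attribute recording the tag used per trait.
#' @export
prepare_traits <- function(phenotypes, traits = NULL,
                           transform_mode = c("canonical", "auto")) {
  transform_mode <- match.arg(transform_mode)
  if (is.null(traits)) {
    traits <- ems_traits()
    traits <- traits[traits$trait %in% names(phenotypes), , drop = FALSE]
  }
  out <- data.frame(sample = phenotypes$sample, stringsAsFactors = FALSE)
  tags <- character(nrow(traits))
  for (i in seq_len(nrow(traits))) {
    tn <- traits$trait[i]
    y <- phenotypes[[tn]]
    if (identical(traits$type[i], "binary")) {
      tag <- "identity"
    } else if (transform_mode == "canonical") {
      tag <- traits$transform[i]
    } else {
      tag <- choose_transform(y, mode = "auto")
    }
    yt <- apply_transform(y, tag)
    fit <- fit_random_intercept(yt, phenotypes)
    out[[tn]] <- residualize(yt, phenotypes, fit)
    tags[i] <- tag
  }
  attr(out, "transforms") <- stats::setNames(tags, traits$trait)
  out
}
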