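## Biomass apportioning, cumulative yield thresholds, width-based
## prediction of dry biomass, subsampling-error simulation.

#' Apportion a plant's dry biomass to its inflorescences
#'
#' Each plant gets a single density (g per cm^2) = IDB / TIC; every
#' inflorescence's weight is density times its 2-D size IS, so the
#' weights sum exactly to IDB.
#'
#' @param records data.frame of the plant's object records (needs
#'   `object_id`, `IS_cm2`).
#' @param IDB_g the plant's inflorescence dry biomass, grams.
#' @param plant_id identifier copied into the output.
#' @return data.frame with `plant_id`, `object_id`, `IS_cm2`, `weight_g`
#'   and attribute `"density_g_cm2"`.
#' @examples
#' rec <- data.frame(object_id = 1:3, IS_cm2 = c(2, 3, 5))
#' apportionWeights(rec, IDB_g = 100)$weight_g  # 20 30 50
#' @export
apportionWeights <- function(records, IDB_g, plant_id = "plant") {
  if (is.na(IDB_g)) stop("IDB is missing; weights require a measured biomass")
  if (IDB_g <= 0) stop("IDB must be positive")
  TIC <- sum(records$IS_cm2)
  if (!length(records$IS_cm2) || TIC <= 0) stop("TIC must be positive")
  density <- IDB_g / TIC
  out <- data.frame(plant_id = plant_id, object_id = records$object_id,
                    IS_cm2 = records$IS_cm2,
                    weight_g = density * records$IS_cm2)
  attr(out, "density_g_cm2") <- density
  out
}

#' Percent of inflorescences needed to reach a cumulative yield fraction
#'
#' Sorts weights in decreasing order (ties broken by object id) and finds
#' the minimal count k of largest inflorescences whose cumulative weight
#' reaches fraction `q` of the total; returns 100*k/N, the percent of the
#' plant's inflorescence count that must be processed.
#'
#' @param weights numeric vector of per-inflorescence weights (grams).
#' @param q target cumulative yield fraction in (0, 1].
#' @param object_id optional ids used for deterministic tie-breaking
#'   (defaults to input position).
#' @return list with `percent` (100*k/N), `k` and `N`.
#' @examples
#' yieldThresholdFraction(c(9, 1), 0.75)$percent  # 50: one object suffices
#' @export
yieldThresholdFraction <- function(weights, q, object_id = seq_along(weights)) {
  if (!length(weights)) stop("weights is empty")
  if (q <= 0 || q > 1) stop("q must lie in (0, 1]")
  ord <- order(-weights, object_id)
  cum <- cumsum(weights[ord])
  k <- which(cum >= q * cum[length(cum)] - 1e-12)[1]
  list(percent = 100 * k / length(weights), k = k, N = length(weights))
}

#' Mean width of the k longest inflorescences
#'
#' Selects the k records with the largest length IL (ties broken by
#' larger IW, then by object id) and returns the arithmetic mean of
#' their widths IW.  When fewer than k records exist, all are used with
#' a warning.
#'
#' @param records data.frame with `IL_cm`, `IW_cm` and `object_id`.
#' @param k how many longest inflorescences to average (default 20).
#' @return list with `mean_IW` (cm), `k_used` and the selected
#'   `records` subset.
#' @export
topLongestMeanWidth <- function(records, k = 20L) {
  if (!is.data.frame(records) || nrow(records) < 1L) stop("records is empty")
  if (k < 1L) stop("k must be >= 1")
  if (nrow(records) < k) {
    warning("only ", nrow(records), " records available; using all")
    k <- nrow(records)
  }
  ord <- order(-records$IL_cm, -records$IW_cm, records$object_id)
  sel <- records[ord[seq_len(k)], , drop = FALSE]
  list(mean_IW = mean(sel$IW_cm), k_used = k, records = sel)
}

#' Width-based yield prediction model with the published coefficients
#'
#' Returns the shipped defaults: IDB[g] = 59.14 * meanIW[cm] - 134.97,
#' where meanIW is the average width of the plant's 20 longest
#' inflorescences, fitted for plants with meanIW > 2.5 cm.  These
#' coefficients are environment-specific — widths respond strongly to
#' cultivation conditions — so treat them as a starting point and refit
#' on local data ([refitPrediction()]) whenever paired width/biomass
#' records exist.
#'
#' @return a [PredictionModel-class] with provenance `"paper_default"`.
#' @export
defaultPredictionModel <- function() {
  new("PredictionModel", slope = 59.14, intercept = -134.97,
      kLongest = 20L, minMeanIW = 2.5, provenance = "paper_default")
}

#' Predict plant dry biomass from mean top-inflorescence width
#'
#' Affine prediction intercept + slope * meanIW.  The model is meant for
#' fresh-equivalent widths; widths measured on dried material should be
#' mapped back with [applyCalibration()] direction `"dry_to_fresh"`
#' first.
#'
#' @param mean_IW mean width (cm) of the plant's k longest
#'   inflorescences, as from [topLongestMeanWidth()].
#' @param model a [PredictionModel-class] (default: the published
#'   coefficients).
#' @return predicted IDB in grams (may be negative for widths far below
#'   the fitted domain; a warning flags widths at or below
#'   `model@minMeanIW`).
#' @examples
#' predictIdb(3.0)  # 59.14*3 - 134.97 = 42.45 g
#' @export
predictIdb <- function(mean_IW, model = defaultPredictionModel()) {
  stopifnot(is(model, "PredictionModel"))
  if (any(!is.finite(mean_IW)) || any(mean_IW <= 0))
    stop("mean_IW must be positive")
  if (any(mean_IW <= model@minMeanIW))
    warning("mean_IW at or below the fitted domain (", model@minMeanIW,
            " cm); prediction is an extrapolation")
  model@intercept + model@slope * mean_IW
}

#' Refit the width-based yield model on local data
#'
#' Ordinary least squares of IDB on mean top-inflorescence width over
#' plants inside the fit domain (mean IW above `min_mean_IW`), with the
#' model F-statistic on (1, n-2) degrees of freedom.
#'
#' @param table data.frame with columns `mean_IW` (cm, fresh-equivalent)
#'   and `IDB_g`; if a `state` column is present it must be
#'   "fresh" (map dried widths back first, see [applyCalibration()]).
#' @param min_mean_IW fit-domain filter in cm (default 2.5).
#' @param k_longest recorded in the returned model (default 20).
#' @return list with `model` (a [PredictionModel-class], provenance
#'   `"refitted"`), `r_squared`, `F`, `df`, `n`.
#' @export
refitPrediction <- function(table, min_mean_IW = 2.5, k_longest = 20L) {
  if (!all(c("mean_IW", "IDB_g") %in% names(table)))
    stop("table needs columns mean_IW and IDB_g")
  if ("state" %in% names(table) && any(table$state != "fresh"))
    stop("widths must be fresh-equivalent; apply dry_to_fresh calibration first")
  d <- table[is.finite(table$mean_IW) & is.finite(table$IDB_g) &
             table$mean_IW > min_mean_IW, ]
  if (nrow(d) < 3L) stop("fewer than 3 plants inside the fit domain")
  if (stats::var(d$mean_IW) == 0) stop("zero width variance")
  fit <- stats::lm(IDB_g ~ mean_IW, data = d)
  sm <- summary(fit)
  model <- new("PredictionModel", slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               kLongest = as.integer(k_longest), minMeanIW = min_mean_IW,
               provenance = "refitted")
  list(model = model, r_squared = sm$r.squared,
       F = unname(sm$fstatistic[1]),
       df = unname(sm$fstatistic[2:3]), n = nrow(d))
}

#' Subsampling error simulation for width measurement
#'
#' Emulates measuring only m of the k longest inflorescences: draws
#' `rounds` random subsamples of size m without replacement from the k
#' top widths and summarises how far the subsample means stray from the
#' full-k mean.
#'
#' @param top_widths numeric vector of the k top widths (cm).
#' @param m subsample size, 1 <= m <= k.
#' @param rounds number of sampling rounds (default 10).
#' @param seed integer seed for reproducibility.
#' @return list with `means` (length `rounds`), `full_mean`, `min`,
#'   `max`, and `max_rel_dev` (largest |mean - full_mean| / full_mean).
#' @export
samplingSimulation <- function(top_widths, m, rounds = 10L, seed = 1L) {
  k <- length(top_widths)
  if (m < 1L || m > k) stop("m must lie in 1..k")
  if (rounds < 1L) stop("rounds must be >= 1")
  set.seed(seed)
  means <- vapply(seq_len(rounds), function(i)
    mean(top_widths[sample.int(k, m)]), numeric(1))
  fm <- mean(top_widths)
  list(means = means, full_mean = fm, min = min(means), max = max(means),
       max_rel_dev = if (fm != 0) max(abs(means - fm)) / abs(fm) else 0)
}
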