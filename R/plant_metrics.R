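## Per-plant aggregation, fresh/dry calibration, heritability, correlations.

.traitCols <- c("IS_cm2", "IL_cm", "IW_cm", "CH_cm2", "HP_cm", "ISH")

#' Summarize a plant's object records
#'
#' Aggregates one plant's per-inflorescence records: inflorescence number
#' IN, total inflorescence coverage TIC = sum of IS, and mean/sd (n-1
#' denominator) for each trait.  Degenerate objects (single-pixel or
#' collinear, ISH undefined) are excluded from the ISH mean/sd only.
#'
#' @param records data.frame of object records as from [measureObjects()].
#' @param plant_id,genotype_id,state plant metadata; `state` is `"fresh"`
#'   or `"dry"`.
#' @param IDB_g inflorescence dry biomass in grams (NA until weighed).
#' @param PH_cm,DTM_d optional plant height (cm) and days to maturation.
#' @return one-row data.frame (a PlantSummary): identifiers, `IN`,
#'   `TIC_cm2`, `<trait>_mean` and `<trait>_sd` for IS, IL, IW, CH, HP and
#'   ISH, then `IDB_g`, `PH_cm`, `DTM_d`.  sd columns are NA when fewer
#'   than 2 contributing records exist.
#' @examples
#' rec <- data.frame(object_id = 1:3, pixel_count = c(800, 1200, 2000),
#'   IS_cm2 = c(2, 3, 5), IL_cm = c(2.4, 2.9, 3.8), IW_cm = c(1.2, 1.6, 2.1),
#'   CH_cm2 = c(2.2, 3.3, 5.4), HP_cm = c(6, 7, 9),
#'   ISH = c(0.5, 0.55, 0.55), degenerate = FALSE)
#' summarizePlant(rec, "p1", "g1", "dry", IDB_g = 50)
#' @export
summarizePlant <- function(records, plant_id, genotype_id,
                           state = c("fresh", "dry"),
                           IDB_g = NA_real_, PH_cm = NA_real_,
                           DTM_d = NA_real_) {
  state <- match.arg(state)
  if (!is.data.frame(records) || nrow(records) < 1L)
    stop("records must contain at least one object")
  miss <- setdiff(.traitCols, names(records))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  degen <- if ("degenerate" %in% names(records)) records$degenerate
           else is.na(records$ISH)
  out <- data.frame(plant_id = plant_id, genotype_id = genotype_id,
                    state = state, IN = nrow(records),
                    TIC_cm2 = sum(records$IS_cm2))
  for (tc in .traitCols) {
    v <- if (tc == "ISH") records[[tc]][!degen] else records[[tc]]
    out[[paste0(tc, "_mean")]] <- if (length(v)) mean(v) else NA_real_
    out[[paste0(tc, "_sd")]] <- if (length(v) >= 2L) stats::sd(v) else NA_real_
  }
  out$IDB_g <- IDB_g; out$PH_cm <- PH_cm; out$DTM_d <- DTM_d
  out
}

#' Fit per-trait fresh-to-dry linear calibration
#'
#' For plants imaged in both states, fits ordinary least squares of the
#' dry value on the fresh value for every shared trait column, recording
#' each trendline's R-squared.  A trait is calibratable only when its
#' R-squared exceeds the gate (default 0.9); others are retained but
#' flagged, and [applyCalibration()] refuses to use them.
#'
#' @param fresh,dry data.frames of per-plant summaries in the two states,
#'   matched by `plant_id`; every shared numeric column other than
#'   identifiers is treated as a trait.
#' @param r2_gate minimum R-squared for a usable trendline.
#' @return a [CalibrationMap-class].
#' @export
fitFreshDryCalibration <- function(fresh, dry, r2_gate = 0.9) {
  common <- intersect(fresh$plant_id, dry$plant_id)
  if (length(common) < 3L) stop("need at least 3 dual-state plants")
  f <- fresh[match(common, fresh$plant_id), , drop = FALSE]
  d <- dry[match(common, dry$plant_id), , drop = FALSE]
  traits <- intersect(names(f)[vapply(f, is.numeric, logical(1))],
                      names(d)[vapply(d, is.numeric, logical(1))])
  traits <- setdiff(traits, c("plant_id", "genotype_id"))
  if (!length(traits)) stop("no shared numeric trait columns")
  rows <- lapply(traits, function(tr) {
    x <- f[[tr]]; y <- d[[tr]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L)
      return(data.frame(trait = tr, slope = NA_real_, intercept = NA_real_,
                        r_squared = NA_real_, calibratable = FALSE))
    if (stats::var(x[ok]) == 0) stop("zero fresh variance for trait ", tr)
    fit <- stats::lm(y[ok] ~ x[ok])
    r2 <- summary(fit)$r.squared
    data.frame(trait = tr, slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]), r_squared = r2,
               calibratable = r2 > r2_gate)
  })
  new("CalibrationMap", table = do.call(rbind, rows),
      nPairs = length(common), r2Gate = r2_gate)
}

#' Map a plant summary between fresh and dry scales
#'
#' Applies the per-trait linear trendline (`dry = slope * fresh +
#' intercept`) to every calibrated trait column present in the summary;
#' `dry_to_fresh` inverts the map.  The `state` field is updated.
#'
#' @param summary one- or multi-row data.frame of plant summaries.
#' @param cal a [CalibrationMap-class].
#' @param direction `"fresh_to_dry"` or `"dry_to_fresh"`.
#' @return the transformed summary data.frame.
#' @export
applyCalibration <- function(summary, cal,
                             direction = c("fresh_to_dry", "dry_to_fresh")) {
  direction <- match.arg(direction)
  stopifnot(is(cal, "CalibrationMap"))
  from <- if (direction == "fresh_to_dry") "fresh" else "dry"
  if (!all(summary$state == from))
    stop("summary state must be '", from, "' for direction ", direction)
  tab <- cal@table
  traits <- intersect(tab$trait, names(summary))
  if (!length(traits)) stop("no calibrated trait columns found in summary")
  out <- summary
  for (tr in traits) {
    row <- tab[tab$trait == tr, ]
    if (!isTRUE(row$calibratable))
      stop("trait '", tr, "' is not calibratable (R^2 <= ", cal@r2Gate, ")")
    out[[tr]] <- if (direction == "fresh_to_dry")
      row$slope * summary[[tr]] + row$intercept
    else
      (summary[[tr]] - row$intercept) / row$slope
  }
  out$state <- if (direction == "fresh_to_dry") "dry" else "fresh"
  out
}

#' Broad-sense heritability from clonal replicates
#'
#' Estimates H^2 = V_G / V_P by a one-way random-effects analysis of
#' variance over genotype groups (clonal repeatability).  With mean
#' squares MS_B between and MS_W within genotypes and the unbalanced
#' design coefficient k1 = (N - sum(n_i^2)/N)/(G - 1):
#' V_G = (MS_B - MS_W)/k1 (truncated at 0), V_P = V_G + MS_W.
#'
#' @param table data.frame with a `genotype_id` column and the trait.
#' @param trait name of the trait column.
#' @return list with `H2`, `V_G`, `V_W`, `k1`, `G` (genotype count) and
#'   `N` (plant count).  `H2` lies in [0, 1].
#' @export
broadSenseHeritability <- function(table, trait) {
  y <- table[[trait]]
  g <- factor(table$genotype_id)
  ok <- is.finite(y) & !is.na(g)
  y <- y[ok]; g <- droplevels(g[ok])
  G <- nlevels(g); N <- length(y)
  if (G < 2L) stop("need at least 2 genotypes")
  ni <- tabulate(g)
  if (max(ni) < 2L) stop("no within-genotype replication")
  ## only the mean squares are used; anova()'s perfect-fit warning
  ## concerns the F-test, which this estimator never consults
  ms <- suppressWarnings(anova(stats::lm(y ~ g))[["Mean Sq"]])
  MSB <- ms[1]; MSW <- ms[2]
  k1 <- (N - sum(ni^2) / N) / (G - 1)
  VG <- max((MSB - MSW) / k1, 0)
  VP <- VG + MSW
  H2 <- if (VP > 0) VG / VP else 1
  list(H2 = H2, V_G = VG, V_W = MSW, k1 = k1, G = G, N = N)
}

#' Pairwise trait correlation matrix with significance blanking
#'
#' Pearson correlations over pairwise-complete observations, with
#' two-sided t-test p-values; the `r_signif` matrix blanks (NA)
#' coefficients whose p-value exceeds `alpha`, mirroring the standard
#' presentation of phenotypic correlation matrices.
#'
#' @param table data.frame of plant or genotype summaries.
#' @param traits character vector of trait column names.
#' @param alpha significance cutoff for blanking (default 0.05).
#' @return list of three matrices: `r`, `p`, `r_signif`.
#' @export
correlationMatrix <- function(table, traits, alpha = 0.05) {
  k <- length(traits)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    x <- table[[traits[i]]]; y <- table[[traits[j]]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L) next
    if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) next  # constant trait: flagged NA
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  rs <- r
  rs[!is.na(p) & p > alpha] <- NA_real_
  list(r = r, p = p, r_signif = rs)
}
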