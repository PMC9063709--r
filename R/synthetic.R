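## Ground-truthed synthetic scenes and plant populations.  The scene
## generator renders non-overlapping filled superellipses with a known
## blue-band contrast; the population generator draws genotype/plant
## variance components, right-skewed object sizes and size-proportional
## biomass so that every downstream statistic has a known truth.

#' Parameters of a synthetic inflorescence scene
#'
#' Defaults emulate a processed-inflorescence photograph: a bright
#' background and dark plant matter in the blue band (background 200,
#' object 60 of 255), mild sensor noise, a 0.05 cm/px scale (a 12 MP
#' frame over a ~60 cm board), and object semi-axes of 0.75-3 cm.
#'
#' @param n_objects number of inflorescences to place.
#' @param width_px,height_px frame size in pixels.
#' @param cm_per_pixel scale, cm per pixel edge.
#' @param a_range_cm,b_range_cm ranges of the semi-major and semi-minor
#'   axes (cm); draws enforce a >= b.
#' @param squareness_range superellipse exponents (2 = pure ellipse;
#'   slightly above rounds toward a rectangle, exercising segmentation
#'   beyond the ideal-ellipse case).  The default cap of 2.2 keeps the
#'   moment-ellipse axes of the rendered shape within ~1.8% of the
#'   nominal 2a/2b, so the 3% axis-recovery tolerance retains margin for
#'   digitization and segmentation noise.
#' @param background_blue,object_blue blue-band levels (0-255).
#' @param noise_sd additive Gaussian pixel noise, gray levels.
#' @param shading if TRUE, a linear horizontal illumination gradient of
#'   +/-10 gray levels is added.
#' @return list of scene-truth parameters.
#' @export
sceneTruth <- function(n_objects = 12L, width_px = 900L, height_px = 700L,
                       cm_per_pixel = 0.05,
                       a_range_cm = c(1.2, 3), b_range_cm = c(0.75, 1.6),
                       squareness_range = c(2, 2.2),
                       background_blue = 200, object_blue = 60,
                       noise_sd = 6, shading = FALSE) {
  stopifnot(n_objects >= 1, cm_per_pixel > 0,
            all(a_range_cm > 0), all(b_range_cm > 0))
  list(n_objects = as.integer(n_objects), width_px = as.integer(width_px),
       height_px = as.integer(height_px), cm_per_pixel = cm_per_pixel,
       a_range_cm = a_range_cm, b_range_cm = b_range_cm,
       squareness_range = squareness_range,
       background_blue = background_blue, object_blue = object_blue,
       noise_sd = noise_sd, shading = shading)
}

## render one filled superellipse into the blue matrix; returns pixel count
.renderSuperellipse <- function(blue, cx, cy, a_px, b_px, theta, e, level) {
  r <- ceiling(max(a_px, b_px)) + 2L
  xs <- max(1L, floor(cx - r)):min(ncol(blue), ceiling(cx + r))
  ys <- max(1L, floor(cy - r)):min(nrow(blue), ceiling(cy + r))
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- (dx * cos(theta) + dy * sin(theta)) / a_px
  v <- (-dx * sin(theta) + dy * cos(theta)) / b_px
  inside <- (abs(u)^e + abs(v)^e) <= 1
  blue[ys, xs][inside] <- level
  blue
}

#' Generate a ground-truthed synthetic scene
#'
#' Places non-overlapping filled superellipses fully inside the frame
#' (rejection sampling on bounding circles), renders their blue-band
#' contrast, optionally adds linear shading and Gaussian noise, and
#' returns both the [CalibratedImage-class] and the exact per-object
#' truth table.  Red and green channels carry a flat plausible scene
#' (they are ignored by the blue-band pipeline).
#'
#' @param truth parameter list from [sceneTruth()].
#' @param seed integer seed; identical seeds give identical rasters.
#' @param n_specks number of sub-floor debris specks (2-8 px) to
#'   scatter, emulating leaf fragments that area opening must remove.
#' @return list with `image` (a [CalibratedImage-class]) and `objects`
#'   (data.frame: object index, center, semi-axes in cm and px,
#'   orientation, squareness, expected IL/IW in cm).
#' @export
generateScene <- function(truth = sceneTruth(), seed = 1L, n_specks = 0L) {
  set.seed(seed)
  p <- truth$cm_per_pixel
  W <- truth$width_px; H <- truth$height_px
  placed <- data.frame()
  attempts <- 0L
  while (nrow(placed) < truth$n_objects) {
    attempts <- attempts + 1L
    if (attempts > 2000L * truth$n_objects)
      stop("infeasible packing: could not place ", truth$n_objects,
           " objects in the frame")
    a_cm <- stats::runif(1, truth$a_range_cm[1], truth$a_range_cm[2])
    b_cm <- stats::runif(1, truth$b_range_cm[1], min(truth$b_range_cm[2], a_cm))
    a_px <- a_cm / p; b_px <- b_cm / p
    r_px <- a_px + 3
    cx <- stats::runif(1, r_px + 1, W - r_px - 1)
    cy <- stats::runif(1, r_px + 1, H - r_px - 1)
    if (nrow(placed) &&
        any((placed$cx - cx)^2 + (placed$cy - cy)^2 <
            (placed$a_px + r_px + 2)^2)) next
    placed <- rbind(placed, data.frame(
      cx = cx, cy = cy, a_px = a_px, b_px = b_px, a_cm = a_cm, b_cm = b_cm,
      theta = stats::runif(1, 0, pi),
      e = stats::runif(1, truth$squareness_range[1], truth$squareness_range[2])))
  }
  blue <- matrix(truth$background_blue, H, W)
  for (i in seq_len(nrow(placed)))
    blue <- .renderSuperellipse(blue, placed$cx[i], placed$cy[i],
                                placed$a_px[i], placed$b_px[i],
                                placed$theta[i], placed$e[i],
                                truth$object_blue)
  if (n_specks > 0L) {
    for (s in seq_len(n_specks)) {
      repeat {  # keep specks clear of objects so they stay separate components
        sx <- sample.int(W - 4L, 1L); sy <- sample.int(H - 4L, 1L)
        if (all((placed$cx - sx)^2 + (placed$cy - sy)^2 >
                (placed$a_px + 12)^2)) break
      }
      npx <- sample(2:8, 1L)
      px <- unique(cbind(sx + sample(0:2, npx, TRUE),
                         sy + sample(0:2, npx, TRUE)))
      blue[cbind(px[, 2], px[, 1])] <- truth$object_blue
    }
  }
  if (isTRUE(truth$shading))
    blue <- blue + matrix(rep(seq(-10, 10, length.out = W), each = H), H, W)
  if (truth$noise_sd > 0)
    blue <- blue + matrix(stats::rnorm(H * W, 0, truth$noise_sd), H, W)
  blue <- pmin(pmax(round(blue), 0), 255)
  px3 <- array(0, c(H, W, 3))
  px3[, , 1] <- 120; px3[, , 2] <- 130  # flat R/G; pipeline uses blue only
  px3[, , 3] <- blue
  img <- new("CalibratedImage", pixels = px3, cmPerPixel = p,
             imageId = sprintf("synthetic_scene_seed%d", seed))
  objects <- data.frame(object = seq_len(nrow(placed)),
                        cx_px = placed$cx, cy_px = placed$cy,
                        a_cm = placed$a_cm, b_cm = placed$b_cm,
                        theta = placed$theta, squareness = placed$e,
                        IL_cm = 2 * placed$a_cm, IW_cm = 2 * placed$b_cm)
  list(image = img, objects = objects)
}

#' Parameters of a synthetic plant population
#'
#' Defaults emulate the structure of a controlled-environment cannabis
#' trial: ~119 genotypes with 4 clonal replicates; 200-300 inflorescences
#' per plant (Poisson); right-skewed per-object sizes (log-normal lengths
#' with shape ratios around 0.6, areas pi/4*IL*IW of 3-5 cm^2 on
#' average); dry biomass proportional to total coverage at ~0.1 g/cm^2
#' with 4% multiplicative noise (which reproduces the near-unity
#' TIC-IDB correlation); genotype and plant variance components on the
#' log-length scale.
#'
#' @param G genotype count.
#' @param clones clonal replicates per genotype.
#' @param lambda_objects mean inflorescence count per plant.
#' @param meanlog_IL,sdlog_IL log-normal parameters of object length (cm).
#' @param V_G,V_E genotype and plant-level variance components added to
#'   the log-length location (dimensionless, log scale).
#' @param shape_mean,shape_sd mean and sd of the per-object width/length
#'   ratio (truncated to (0.05, 1)).
#' @param density_g_cm2 biomass density, grams per cm^2 of coverage.
#' @param idb_noise_sd relative sd of the multiplicative IDB noise.
#' @return list of population-truth parameters.
#' @export
populationTruth <- function(G = 119L, clones = 4L, lambda_objects = 250,
                            meanlog_IL = log(2.2), sdlog_IL = 0.35,
                            V_G = 0.01, V_E = 0.02,
                            shape_mean = 0.6, shape_sd = 0.12,
                            density_g_cm2 = 0.1, idb_noise_sd = 0.04) {
  stopifnot(G >= 2, clones >= 1, V_G >= 0, V_E >= 0, lambda_objects > 0)
  list(G = as.integer(G), clones = as.integer(clones),
       lambda_objects = lambda_objects, meanlog_IL = meanlog_IL,
       sdlog_IL = sdlog_IL, V_G = V_G, V_E = V_E,
       shape_mean = shape_mean, shape_sd = shape_sd,
       density_g_cm2 = density_g_cm2, idb_noise_sd = idb_noise_sd)
}

#' Generate a ground-truthed plant population
#'
#' Draws genotype effects Normal(0, V_G) and plant deviations
#' Normal(0, V_E) on the log-length location; per-plant object counts
#' Poisson(lambda); per-object lengths log-normal and widths as a
#' truncated-normal shape ratio times length; object areas pi/4*IL*IW;
#' TIC as their sum and IDB = density * TIC * (1 + noise).
#'
#' @param truth parameter list from [populationTruth()].
#' @param seed integer seed.
#' @param keep_objects if TRUE (default) the per-object records are
#'   returned (can be large: G * clones * lambda rows).
#' @return list with `plants` (one row per plant: ids, state = "dry",
#'   `IN`, `TIC_cm2`, trait means/sds, `IDB_g`, `mean_IW` of the 20
#'   longest) and optionally `objects` (per-object records).
#' @export
generatePopulation <- function(truth = populationTruth(), seed = 1L,
                               keep_objects = TRUE) {
  set.seed(seed)
  gEff <- stats::rnorm(truth$G, 0, sqrt(truth$V_G))
  plants <- list(); objects <- list()
  idx <- 0L
  for (g in seq_len(truth$G)) for (cl in seq_len(truth$clones)) {
    idx <- idx + 1L
    pid <- sprintf("g%03d_c%d", g, cl)
    loc <- truth$meanlog_IL + gEff[g] + stats::rnorm(1, 0, sqrt(truth$V_E))
    n <- max(1L, stats::rpois(1, truth$lambda_objects))
    IL <- stats::rlnorm(n, loc, truth$sdlog_IL)
    sh <- pmin(pmax(stats::rnorm(n, truth$shape_mean, truth$shape_sd),
                    0.05), 1)
    IW <- sh * IL
    IS <- pi / 4 * IL * IW
    TIC <- sum(IS)
    IDB <- truth$density_g_cm2 * TIC *
      (1 + stats::rnorm(1, 0, truth$idb_noise_sd))
    rec <- data.frame(plant_id = pid, object_id = seq_len(n),
                      IS_cm2 = IS, IL_cm = IL, IW_cm = IW,
                      CH_cm2 = IS * 1.05, HP_cm = pi * (IL + IW) / 2 * 1.02,
                      ISH = IW / IL, degenerate = FALSE)
    tw <- topLongestMeanWidth(rec, min(20L, n))
    sm <- summarizePlant(rec, pid, sprintf("g%03d", g), "dry", IDB_g = IDB)
    sm$mean_IW <- tw$mean_IW
    plants[[idx]] <- sm
    if (keep_objects) objects[[idx]] <- rec
  }
  out <- list(plants = do.call(rbind, plants))
  if (keep_objects) out$objects <- do.call(rbind, objects)
  out
}

#' Simulate clonal trait values with known variance components
#'
#' Direct trait-level simulation for heritability studies: genotype
#' effects Normal(0, V_G) plus plant deviations Normal(0, V_E) around a
#' grand mean, so the true broad-sense heritability is V_G/(V_G + V_E).
#'
#' @param G genotypes; @param clones clones per genotype.
#' @param V_G,V_E genotype and environmental variance components.
#' @param mean grand mean of the trait.
#' @param seed integer seed.
#' @return data.frame with `plant_id`, `genotype_id`, `value`.
#' @export
generateTraitPopulation <- function(G = 100L, clones = 4L, V_G = 0.4,
                                    V_E = 0.6, mean = 0, seed = 1L) {
  set.seed(seed)
  gEff <- rep(stats::rnorm(G, 0, sqrt(V_G)), each = clones)
  data.frame(
    plant_id = sprintf("g%03d_c%d", rep(seq_len(G), each = clones),
                       rep(seq_len(clones), G)),
    genotype_id = sprintf("g%03d", rep(seq_len(G), each = clones)),
    value = mean + gEff + stats::rnorm(G * clones, 0, sqrt(V_E)))
}
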