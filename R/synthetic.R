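# Synthetic image + metadata generator emulating the PAD-UFES-20 layout.
#
# Class signal in each modality is injected by linear interpolation between
# one shared distribution and six class-specific distributions: coefficient
# alpha controls the image modality, beta the metadata modality. alpha = 0
# (or beta = 0) makes that modality's distributions identical across
# classes; 1 gives fully class-specific distributions. This one-knob
# parameterization supports ordering experiments over modality
# informativeness.

#' Class counts of the reference dataset composition
#'
#' The deposited dataset's composition (2,298 lesions): 730 ACK, 845 BCC,
#' 52 MEL, 244 NEV, 192 SCC, 235 SEK. With `total` different from 2298 the
#' counts are rescaled proportionally (largest-remainder rounding; every
#' class keeps at least one sample).
#'
#' @param total Desired total sample count.
#' @return Named integer vector of six class counts summing to `total`.
#' @export
pad_ufes_proportions <- function(total = 2298L) {
  counts <- c(ACK = 730, BCC = 845, MEL = 52, NEV = 244, SCC = 192, SEK = 235)
  if (total == sum(counts)) return(counts)
  raw <- counts * total / sum(counts)
  n <- pmax(floor(raw), 1)
  rem <- total - sum(n)
  if (rem > 0) {
    frac <- raw - floor(raw)
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    n[add] <- n[add] + 1
  } else if (rem < 0) {
    sub <- order(n, decreasing = TRUE)[seq_len(-rem)]
    n[sub] <- n[sub] - 1
  }
  stats::setNames(as.integer(n), names(counts))
}

#' Specification of a synthetic dataset
#'
#' @param n_per_class Six class counts in [lesion_classes()] order, or the
#'   string `"pad_ufes_proportions"` for the deposited dataset's composition.
#' @param image_size Image side length in pixels.
#' @param alpha Image-modality informativeness in `[0, 1]`.
#' @param beta Metadata-modality informativeness in `[0, 1]`.
#' @param missing_rate Probability that any one metadata value is missing.
#' @param seed Generation seed; the dataset is bit-reproducible from the
#'   spec alone.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_per_class = rep(60L, 6L), image_size = 64L,
                       alpha = 0.5, beta = 0.5, missing_rate = 0.05,
                       seed = 1L) {
  if (identical(n_per_class, "pad_ufes_proportions")) {
    n_per_class <- pad_ufes_proportions()
  }
  n_per_class <- as.integer(n_per_class)
  stopifnot(length(n_per_class) == 6L, sum(n_per_class) >= 6L,
            alpha >= 0, alpha <= 1, beta >= 0, beta <= 1,
            missing_rate >= 0, missing_rate < 1)
  structure(list(n_per_class = stats::setNames(n_per_class, lesion_classes()),
                 image_size = as.integer(image_size), alpha = alpha,
                 beta = beta, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# mix(shared, specific, w): the signal interpolation used throughout.
mix <- function(shared, specific, w) (1 - w) * shared + w * specific

# --- class-conditional metadata archetypes ---------------------------------
# Chosen once for dermatological plausibility: actinic damage classes (ACK,
# SCC) affect older, sun-exposed, low-phototype patients; MEL/NEV lesions
# change and grow; BCC/SCC bleed and hurt; NEV patients are younger.

meta_archetypes <- function() {
  cls <- lesion_classes()
  bool_rates <- rbind( #           ACK   BCC   MEL   NEV   SCC   SEK
    smoking             = c(0.35, 0.30, 0.20, 0.15, 0.45, 0.25),
    drinking            = c(0.30, 0.30, 0.25, 0.25, 0.35, 0.30),
    cancer_history      = c(0.30, 0.35, 0.40, 0.15, 0.35, 0.20),
    skin_cancer_history = c(0.35, 0.40, 0.45, 0.10, 0.40, 0.15),
    pesticide           = c(0.50, 0.25, 0.15, 0.10, 0.55, 0.15),
    sewage_system       = c(0.45, 0.70, 0.80, 0.85, 0.40, 0.75),
    piped_water         = c(0.55, 0.75, 0.85, 0.90, 0.50, 0.80),
    itch                = c(0.70, 0.45, 0.25, 0.10, 0.60, 0.40),
    grew                = c(0.30, 0.55, 0.85, 0.15, 0.70, 0.35),
    hurt                = c(0.25, 0.45, 0.30, 0.05, 0.65, 0.15),
    changed             = c(0.25, 0.40, 0.85, 0.10, 0.55, 0.30),
    bleed               = c(0.20, 0.60, 0.50, 0.05, 0.65, 0.15),
    elevation           = c(0.30, 0.65, 0.45, 0.55, 0.50, 0.80)
  )
  colnames(bool_rates) <- cls
  fitz <- rbind(ACK = c(0.30, 0.35, 0.20, 0.10, 0.04, 0.01),
                BCC = c(0.20, 0.30, 0.25, 0.15, 0.07, 0.03),
                MEL = c(0.30, 0.30, 0.20, 0.12, 0.06, 0.02),
                NEV = c(0.10, 0.20, 0.25, 0.25, 0.12, 0.08),
                SCC = c(0.35, 0.35, 0.18, 0.08, 0.03, 0.01),
                SEK = c(0.12, 0.22, 0.28, 0.20, 0.12, 0.06))
  regions <- default_category_sets()$region
  region_pref <- list(ACK = c("FACE", "FOREARM"), BCC = c("NOSE", "FACE"),
                      MEL = c("BACK", "CHEST"), NEV = c("BACK", "ABDOMEN"),
                      SCC = c("FACE", "HAND"), SEK = c("CHEST", "BACK"))
  region_probs <- t(vapply(cls, function(c) {
    p <- rep(0.3 / length(regions), length(regions))
    p[match(region_pref[[c]], regions)] <- 0.35
    p / sum(p)
  }, numeric(length(regions))))
  colnames(region_probs) <- regions
  countries <- default_category_sets()$father_country
  country_probs <- t(vapply(cls, function(c) {
    p <- rep(1, length(countries))
    # European ancestry slightly enriched in the actinic-damage classes
    tilt <- match(c, cls) %in% c(1L, 5L)
    p[match(c("GERMANY", "POMERANIA"), countries)] <-
      if (tilt) 3 else 1
    p[match("BRAZIL", countries)] <- 6
    p / sum(p)
  }, numeric(length(countries))))
  colnames(country_probs) <- countries
  list(
    age_mean = c(ACK = 66, BCC = 62, MEL = 58, NEV = 34, SCC = 69, SEK = 60),
    age_sd = 12,
    d1_mean = c(ACK = 9, BCC = 10, MEL = 7, NEV = 4, SCC = 13, SEK = 6),
    d1_sd = 2.5,
    male_rate = c(ACK = 0.45, BCC = 0.50, MEL = 0.55, NEV = 0.40,
                  SCC = 0.65, SEK = 0.50),
    bool_rates = bool_rates,
    fitz = fitz, region = region_probs, country = country_probs
  )
}

sample_categorical <- function(categories, probs) {
  categories[sample.int(length(categories), 1L, prob = probs)]
}

# One metadata record for class index c at informativeness beta.
generate_record <- function(c, beta, arche, missing_rate) {
  shared_age <- mean(arche$age_mean); shared_d1 <- mean(arche$d1_mean)
  age <- stats::rnorm(1, mix(shared_age, arche$age_mean[[c]], beta), arche$age_sd)
  age <- round(min(max(age, 18), 95))
  d1 <- stats::rnorm(1, mix(shared_d1, arche$d1_mean[[c]], beta), arche$d1_sd)
  d1 <- round(min(max(d1, 1), 30), 1)
  d2 <- round(min(max(0.8 * d1 + stats::rnorm(1, 0, 1), 0.5), 30), 1)
  rec <- list(age = age, diameter_1 = d1, diameter_2 = d2)
  shared_bool <- rowMeans(arche$bool_rates)
  for (b in rownames(arche$bool_rates)) {
    rec[[b]] <- stats::runif(1) < mix(shared_bool[[b]],
                                      arche$bool_rates[b, c], beta)
  }
  p_male <- mix(mean(arche$male_rate), arche$male_rate[[c]], beta)
  rec$gender <- if (stats::runif(1) < p_male) "male" else "female"
  mix_probs <- function(m) {
    p <- mix(colMeans(m), m[c, ], beta)
    p / sum(p)
  }
  rec$fitzpatrick <- sample_categorical(as.character(1:6), mix_probs(arche$fitz))
  rec$region <- sample_categorical(colnames(arche$region), mix_probs(arche$region))
  rec$father_country <- sample_categorical(colnames(arche$country),
                                           mix_probs(arche$country))
  rec$mother_country <- sample_categorical(colnames(arche$country),
                                           mix_probs(arche$country))
  if (missing_rate > 0) {
    drop <- stats::runif(length(rec)) < missing_rate
    rec[drop] <- NA
  }
  rec
}

# --- class-conditional lesion images ---------------------------------------
# Background skin texture plus one soft-edged elliptical lesion whose color,
# size and border irregularity are class-conditional with separation alpha.

image_archetypes <- function() {
  list(
    color = rbind(ACK = c(0.85, 0.45, 0.40), BCC = c(0.85, 0.58, 0.52),
                  MEL = c(0.25, 0.15, 0.10), NEV = c(0.45, 0.30, 0.20),
                  SCC = c(0.75, 0.35, 0.30), SEK = c(0.55, 0.42, 0.25)),
    radius = c(ACK = 0.15, BCC = 0.18, MEL = 0.16, NEV = 0.11,
               SCC = 0.21, SEK = 0.17),
    rough = c(ACK = 0.15, BCC = 0.10, MEL = 0.45, NEV = 0.05,
              SCC = 0.30, SEK = 0.12)
  )
}

generate_image <- function(c, alpha, size) {
  arche <- image_archetypes()
  base <- c(0.80, 0.62, 0.52) + stats::rnorm(3, 0, 0.02)
  img <- array(0, dim = c(size, size, 3L))
  grad <- outer(seq(-0.5, 0.5, length.out = size),
                seq(-0.5, 0.5, length.out = size),
                function(a, b) a * stats::rnorm(1, 0, 0.05) +
                  b * stats::rnorm(1, 0, 0.05))
  for (ch in 1:3) {
    img[, , ch] <- base[ch] + grad +
      matrix(stats::rnorm(size * size, 0, 0.02), size, size)
  }
  color <- mix(colMeans(arche$color), arche$color[c, ], alpha) +
    stats::rnorm(3, 0, 0.02)
  r0 <- mix(mean(arche$radius), arche$radius[[c]], alpha) *
    stats::runif(1, 0.85, 1.15) * size
  rough <- mix(mean(arche$rough), arche$rough[[c]], alpha)
  cx <- size / 2 + stats::runif(1, -size / 8, size / 8)
  cy <- size / 2 + stats::runif(1, -size / 8, size / 8)
  ecc <- stats::runif(1, 0.75, 1.3)
  ph1 <- stats::runif(1, 0, 2 * pi); ph2 <- stats::runif(1, 0, 2 * pi)
  xs <- matrix(rep(seq_len(size), each = size), size) # column index
  ys <- matrix(rep(seq_len(size), times = size), size) # row index
  dx <- (xs - cx) / ecc
  dy <- (ys - cy) * ecc
  rr <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  redge <- r0 * (1 + 0.3 * rough * sin(3 * th + ph1) +
                   0.2 * rough * sin(5 * th + ph2))
  # soft lesion boundary, ~1.5 px transition
  w <- 1 / (1 + exp((rr - redge) / 1.5))
  inner_tex <- matrix(stats::rnorm(size * size, 0, 0.03), size, size)
  for (ch in 1:3) {
    img[, , ch] <- img[, , ch] * (1 - w) + (color[ch] + inner_tex) * w
  }
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic image + metadata dataset
#'
#' Produces class-conditional lesion images (background skin texture plus a
#' soft-edged elliptical lesion whose color, size and border irregularity
#' carry the class signal, scaled by `alpha`) and class-conditional
#' clinical metadata over the default 21-attribute schema (class-specific
#' means/rates scaled by `beta`). Missing values are injected at
#' `missing_rate` and encode later under the all-zero convention. The
#' dataset regenerates bit-identically from its manifest.
#'
#' @param spec A [synth_spec()].
#' @return Object of class `synth_dataset`: list with `images` (list of
#'   arrays), `records`, `labels` (factor), `ids` and `manifest`.
#' @export
generate_dataset <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  arche <- meta_archetypes()
  n <- sum(spec$n_per_class)
  labels <- factor(rep(lesion_classes(), spec$n_per_class),
                   levels = lesion_classes())
  withr::with_seed(spec$seed, {
    records <- vector("list", n)
    images <- vector("list", n)
    for (i in seq_len(n)) {
      c <- as.integer(labels[i])
      records[[i]] <- generate_record(c, spec$beta, arche, spec$missing_rate)
      images[[i]] <- generate_image(c, spec$alpha, spec$image_size)
    }
  })
  ids <- data.frame(
    patient_id = sprintf("PAT_%04d", seq_len(n)),
    lesion_id = seq_len(n),
    img_id = sprintf("PAT_%04d_%d_%03d.png", seq_len(n), seq_len(n),
                     seq_len(n) %% 1000L)
  )
  structure(list(images = images, records = records, labels = labels,
                 ids = ids, manifest = list(spec = spec)),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  s <- x$manifest$spec
  cat("Synthetic lesion dataset:", length(x$images), "samples,",
      s$image_size, "x", s$image_size, "px\n")
  cat("  alpha (image signal):", s$alpha, "| beta (metadata signal):",
      s$beta, "| missing rate:", s$missing_rate, "| seed:", s$seed, "\n")
  print(table(x$labels))
  invisible(x)
}

#' Tiny deterministic dataset for examples and tests
#'
#' Twelve samples (two per class), 64x64 images, fully informative in both
#' modalities, no missing values, fixed seed.
#'
#' @return A [generate_dataset()] result.
#' @export
worked_fixture <- function() {
  generate_dataset(synth_spec(n_per_class = rep(2L, 6L), image_size = 64L,
                              alpha = 1, beta = 1, missing_rate = 0,
                              seed = 42L))
}
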