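#' Simulate mammogram-like ROI patches with class-dependent lesions
#'
#' Generates seeded synthetic ROI datasets with the statistical structure
#' the pipeline assumes, so every stage is testable without any dataset
#' download. Each patch is a smoothed-noise background rescaled to a
#' mid-gray band, plus (for lesion classes) a centered radial Gaussian bump
#' whose contrast is class dependent; malignant lesions additionally
#' modulate the bump radius sinusoidally with angle (a crude spiculation),
#' and i.i.d. Gaussian pixel noise is added. Intensities are clipped to
#' `[0, 1]`. This emulates class-separable lesion structure, not realistic
#' breast texture.
#'
#' @param n_per_class Patches per class.
#' @param side Patch side in pixels (default 32).
#' @param classes Class names; each needs an entry in `delta`.
#' @param delta Named lesion contrasts (intensity units) per class; classes
#'   named `"malignant"` get spiculation. Default
#'   `c(benign = 0.15, malignant = 0.5)`.
#' @param delta_jitter Relative per-sample contrast variability: each
#'   patch's contrast is `delta * U(1 - delta_jitter, 1 + delta_jitter)`
#'   (default 0.1), mimicking patient-to-patient lesion density variation.
#' @param sigma_bg Gaussian smoothing radius of the background texture (px).
#' @param sigma_n Additive pixel noise standard deviation.
#' @param lesion_sigma Radial scale of the lesion bump (px).
#' @param spic_amplitude,spic_frequency Spiculation radius modulation
#'   (relative amplitude, lobes per turn) for malignant lesions.
#' @param seed Integer seed; same seed, same dataset, bit for bit.
#' @return List with `images` (list of side x side matrices), `labels`
#'   (factor), and `manifest` (data frame: sample_id, label, source,
#'   transform).
#' @export
simulate_rois <- function(n_per_class = 200L, side = 32L,
                          classes = c("benign", "malignant"),
                          delta = c(benign = 0.15, malignant = 0.5),
                          delta_jitter = 0.1,
                          sigma_bg = 4, sigma_n = 0.05,
                          lesion_sigma = side / 5,
                          spic_amplitude = 0.3, spic_frequency = 7, seed = 0) {
  if (sigma_bg <= 0 || sigma_n < 0) stopf("noise scales must be positive")
  if (!all(classes %in% names(delta))) stopf("delta must name every class")
  with_seed(seed, {
    cx <- (side + 1) / 2
    d <- sqrt(outer((seq_len(side) - cx)^2, (seq_len(side) - cx)^2, "+"))
    theta <- atan2(outer(seq_len(side) - cx, rep(1, side)),
                   outer(rep(1, side), seq_len(side) - cx))
    images <- list(); labels <- character(0); ids <- character(0)
    for (cl in classes) {
      for (i in seq_len(n_per_class)) {
        bg <- matrix(stats::rnorm(side^2), side, side)
        bg <- as.matrix(EBImage::gblur(bg, sigma = sigma_bg))
        rng <- range(bg)
        bg <- 0.35 + 0.3 * (bg - rng[[1]]) / max(rng[[2]] - rng[[1]], 1e-12)
        sig <- lesion_sigma
        if (cl == "malignant" && spic_amplitude > 0) {
          phase <- stats::runif(1, 0, 2 * pi)
          sig <- lesion_sigma * (1 + spic_amplitude * sin(spic_frequency * theta + phase))
        }
        amp <- delta[[cl]] * stats::runif(1, 1 - delta_jitter, 1 + delta_jitter)
        img <- bg + amp * exp(-(d / sig)^2 / 2) +
          matrix(stats::rnorm(side^2, sd = sigma_n), side, side)
        id <- sprintf("sim_%s_%04d", cl, i)
        images[[id]] <- clip01(img)
        labels <- c(labels, cl); ids <- c(ids, id)
      }
    }
    list(images = images,
         labels = factor(labels, levels = classes),
         manifest = data.frame(sample_id = ids, label = labels,
                               source = "simulate_rois", transform = "identity",
                               stringsAsFactors = FALSE))
  })
}

#' Simulate a deep-feature-like table with planted structure
#'
#' Emulates the two statistical features of extracted deep-feature matrices
#' that the LR-PCA reduction targets: strong within-group multicollinearity
#' and a low-rank informative subspace. Latent factors `Z` (`n x r`,
#' standard normal) load onto disjoint feature groups
#' (`X = Z W + sigma * noise`; `load` sets the within-group loading, hence
#' within-group correlation), and the binary label follows a logistic model
#' on the first `n_informative` factors:
#' `y ~ Bernoulli(plogis(Z[, 1:n_informative] %*% beta))`. The ground-truth
#' informative directions (unit vectors in feature space) are returned for
#' recovery tests.
#'
#' The factor spectrum is shaped like the decaying eigenvalue profile of
#' real deep-feature covariances: the informative factors occupy the top of
#' the spectrum with per-factor loading multipliers evenly spaced over
#' `informative_scale`, and the non-informative band sits below
#' (`background_scale`). The spacing matters: the label model is a single
#' linear index over the informative factors, so individual factors are
#' only separately identifiable from the labels when the sample principal
#' components align with the factors; well-separated eigenvalues (large
#' gaps within the informative block and between blocks) keep the sample
#' eigenvectors from mixing at moderate n.
#'
#' @param n Samples.
#' @param p Features (a multiple of `r` keeps the groups equal-sized).
#' @param r Latent factors (rank of the signal part).
#' @param n_informative Number of label-driving factors (`<= r`).
#' @param beta Logistic effect per informative factor (scalar or vector).
#'   The default (15) puts the Bayes accuracy near 98%, mirroring the
#'   near-separable geometry of deep features on well-annotated ROIs.
#' @param load Base within-group factor loading.
#' @param sigma Feature noise standard deviation.
#' @param informative_scale Range of loading multipliers for the
#'   informative factor block (default `c(2.6, 1.1)`).
#' @param background_scale Range of loading multipliers for the remaining
#'   factors (default `c(0.55, 0.4)`).
#' @param seed Integer seed.
#' @return List with `x` (n x p), `y` (factor, levels
#'   `c("negative", "positive")`), and `truth` (list: `directions` = p x
#'   n_informative orthonormal matrix of informative feature-space
#'   directions, `informative` = factor indices, plus the config).
#' @export
simulate_features <- function(n = 400L, p = 64L, r = 8L, n_informative = 3L,
                              beta = 15, load = 0.9, sigma = 0.3,
                              informative_scale = c(2.6, 1.1),
                              background_scale = c(0.55, 0.4), seed = 0) {
  if (n_informative > r || r > p) stopf("need n_informative <= r <= p")
  if (n <= r) stopf("need n > r")
  beta <- rep_len(beta, n_informative)
  scale_g <- c(seq(informative_scale[[1]], informative_scale[[2]],
                   length.out = n_informative),
               if (r > n_informative)
                 seq(background_scale[[1]], background_scale[[2]],
                     length.out = r - n_informative))
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n * r), n, r)
    W <- matrix(0, r, p)
    group <- rep(seq_len(r), length.out = p)   # feature j -> factor group
    for (j in seq_len(p)) W[group[[j]], j] <- load * scale_g[[group[[j]]]]
    X <- Z %*% W + matrix(stats::rnorm(n * p, sd = sigma), n, p)
    eta <- drop(Z[, seq_len(n_informative), drop = FALSE] %*% beta)
    y01 <- stats::rbinom(n, 1L, stats::plogis(eta))
    dirs <- vapply(seq_len(n_informative), function(f) {
      v <- W[f, ]
      v / sqrt(sum(v^2))
    }, numeric(p))
    colnames(X) <- sprintf("f%04d", seq_len(p))
    list(x = X,
         y = factor(c("negative", "positive")[y01 + 1L],
                    levels = c("negative", "positive")),
         truth = list(directions = dirs, informative = seq_len(n_informative),
                      group = group,
                      config = list(n = n, p = p, r = r,
                                    n_informative = n_informative, beta = beta,
                                    load = load, sigma = sigma, seed = seed)))
  })
}

#' Write a simulated ROI dataset in the prepared-sample layout
#'
#' Emits the same PNG-per-sample plus tab-separated manifest layout that
#' [prepare_dataset()] produces from real annotated images, so downstream
#' stages cannot tell synthetic from real origin.
#'
#' @param sim Result of [simulate_rois()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_roi_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(sim$images))
    write_image_png(sim$images[[id]], file.path(dir, paste0(id, ".png")))
  man <- file.path(dir, "manifest.tsv")
  utils::write.table(sim$manifest, man, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(man)
}
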