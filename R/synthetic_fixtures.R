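# Synthetic binary-mixture datasets with known ground truth.
#
# The generator emulates the structure of a DES density dataset: a few tens
# of component-1 (HBA) and component-2 (HBD) chemicals, mixtures drawn from
# their cross product at a handful of molar ratios, a temperature series
# per mixture, and a response that is linear in a small set of
# weighted-mixture descriptors plus temperature (negative slope: density
# decreases with temperature) and halide indicators, with additive Gaussian
# noise.

#' Specification of a synthetic binary-mixture dataset
#'
#' Defaults mirror the structure of the motivating DES density data: 17
#' component-1 (HBA) and 42 component-2 (HBD) chemicals, 145 distinct
#' mixtures, a temperature grid from 283.15 to 373.15 K with an 8-point
#' series per mixture (about 1160 records), density-like responses around
#' 1.1 g/cm3 with a negative temperature slope of -5e-4 per kelvin, and an
#' experimental noise level of 0.005 g/cm3.
#'
#' @param n_comp1,n_comp2 numbers of component-1 / component-2 chemicals.
#' @param n_descriptors number of base descriptors per chemical.
#' @param n_mixtures number of distinct (pair, ratio) mixtures sampled from
#'   the cross product.
#' @param ratios list of c(x1, x2) mole-fraction pairs.
#' @param temperatures_K temperature grid (kelvin).
#' @param n_temps_per_mixture length of the per-mixture temperature series.
#' @param true_features names of the weighted-mixture features carrying
#'   signal (base descriptors are named \code{d01}, \code{d02}, ...).
#' @param true_coefficients their coefficients (property units per feature
#'   unit).
#' @param temp_coefficient response slope per kelvin.
#' @param cl_coefficient,br_coefficient shifts for the chloride / bromide
#'   indicator (set to 0 for a purely descriptor-driven response).
#' @param intercept response intercept.
#' @param noise_sd additive Gaussian noise (property units).
#' @param rng_seed integer seed; generation is bit-reproducible given the
#'   seed.
#' @return Object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_comp1 = 17, n_comp2 = 42, n_descriptors = 20,
                           n_mixtures = 145,
                           ratios = list(c(0.5, 0.5), c(2/3, 1/3),
                                         c(0.75, 0.25)),
                           temperatures_K = seq(283.15, 373.15, by = 10),
                           n_temps_per_mixture = 8,
                           true_features = c("d01_pmix", "d02_pmix",
                                             "d03_nmix"),
                           true_coefficients = c(0.06, -0.04, 0.05),
                           temp_coefficient = -5e-4,
                           cl_coefficient = 0.04, br_coefficient = 0.09,
                           intercept = 1.25, noise_sd = 0.005,
                           rng_seed = 1) {
  stopifnot(n_comp1 >= 1, n_comp2 >= 1, n_descriptors >= 1,
            length(true_features) == length(true_coefficients),
            length(true_features) <= 2 * n_descriptors,
            noise_sd >= 0,
            n_temps_per_mixture <= length(temperatures_K),
            n_mixtures <= n_comp1 * n_comp2 * length(ratios))
  if (!all(vapply(ratios, function(r) abs(sum(r) - 1) < 1e-9, TRUE))) {
    stop("each ratio pair must sum to 1", call. = FALSE)
  }
  base <- sprintf("d%02d", seq_len(n_descriptors))
  valid <- c(paste0(base, "_pmix"), paste0(base, "_nmix"))
  bad <- setdiff(true_features, valid)
  if (length(bad)) {
    stop("true_features not generated by this spec: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(
    n_comp1 = n_comp1, n_comp2 = n_comp2, n_descriptors = n_descriptors,
    n_mixtures = n_mixtures, ratios = ratios,
    temperatures_K = temperatures_K,
    n_temps_per_mixture = n_temps_per_mixture,
    true_features = true_features,
    true_coefficients = setNames(true_coefficients, true_features),
    temp_coefficient = temp_coefficient,
    cl_coefficient = cl_coefficient, br_coefficient = br_coefficient,
    intercept = intercept, noise_sd = noise_sd, rng_seed = rng_seed
  ), class = "synthetic_spec")
}

# Draw a descriptor matrix: per-descriptor random location and scale,
# independent Gaussian values per chemical.
draw_components <- function(ids, n_descriptors, loc, scl) {
  m <- vapply(seq_len(n_descriptors), function(d) {
    rnorm(length(ids), mean = loc[d], sd = scl[d])
  }, numeric(length(ids)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(ids))
  rownames(m) <- ids
  colnames(m) <- sprintf("d%02d", seq_len(n_descriptors))
  m
}

# Deterministic response law shared by the modelling and external
# generators.
synthetic_response <- function(records, components, spec, noise = TRUE) {
  feats <- wm_feature_block(records, components, "both")
  y <- spec$intercept +
    drop(feats[, spec$true_features, drop = FALSE] %*%
           spec$true_coefficients) +
    spec$temp_coefficient * records$T_K +
    spec$cl_coefficient * records$has_Cl +
    spec$br_coefficient * records$has_Br
  if (noise && spec$noise_sd > 0) {
    y <- y + rnorm(nrow(records), sd = spec$noise_sd)
  }
  y
}

build_records <- function(pairs, spec, temps_fixed = NULL, id_prefix = "R") {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    temps <- if (is.null(temps_fixed)) {
      sort(sample(spec$temperatures_K, spec$n_temps_per_mixture))
    } else {
      temps_fixed
    }
    ratio <- spec$ratios[[pairs$ratio[i]]]
    data.frame(comp1_id = pairs$comp1_id[i], comp2_id = pairs$comp2_id[i],
               x1 = ratio[1], x2 = ratio[2], T_K = temps,
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rows)
  records$record_id <- sprintf("%s%05d", id_prefix, seq_len(nrow(records)))
  records
}

attach_halides <- function(records, halide_of) {
  flags <- halide_of[records$comp1_id]
  records$has_Cl <- as.numeric(flags == "Cl")
  records$has_Br <- as.numeric(flags == "Br")
  records
}

#' Generate a synthetic mixture dataset with known ground truth
#'
#' Component descriptor vectors are drawn from per-descriptor Gaussians
#' (random location in [-2, 2], scale in [0.5, 1.5]); mixtures are sampled
#' without replacement from the (component-1, component-2, ratio) cross
#' product; each mixture receives a temperature series; the response
#' follows the linear law of the spec plus Gaussian noise.  Component-1
#' chemicals are randomly tagged as chloride, bromide or halide-free salts.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return list with the \code{dataset} (a \code{mixture_dataset}) and the
#'   ground \code{truth}: spec, intercept, and the full coefficient vector
#'   over weighted-mixture features, \code{T_K}, \code{has_Cl},
#'   \code{has_Br}.
#' @export
generate_mixture_data <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$rng_seed, {
    ids1 <- sprintf("HBA%02d", seq_len(spec$n_comp1))
    ids2 <- sprintf("HBD%02d", seq_len(spec$n_comp2))
    loc <- runif(spec$n_descriptors, -2, 2)
    scl <- runif(spec$n_descriptors, 0.5, 1.5)
    components <- draw_components(c(ids1, ids2), spec$n_descriptors, loc, scl)
    halide_of <- setNames(sample(c("none", "Cl", "Br"), spec$n_comp1,
                                 replace = TRUE, prob = c(0.3, 0.5, 0.2)),
                          ids1)

    cand <- expand.grid(comp1_id = ids1, comp2_id = ids2,
                        ratio = seq_along(spec$ratios),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    pairs <- cand[sample.int(nrow(cand), spec$n_mixtures), , drop = FALSE]
    records <- attach_halides(build_records(pairs, spec), halide_of)
    records$y <- synthetic_response(records, components, spec)

    truth <- list(
      spec = spec,
      intercept = spec$intercept,
      coefficients = c(spec$true_coefficients,
                       T_K = spec$temp_coefficient,
                       has_Cl = spec$cl_coefficient,
                       has_Br = spec$br_coefficient),
      descriptor_location = loc, descriptor_scale = scl,
      halide_of = halide_of)
    list(dataset = mixture_dataset(records, components), truth = truth)
  })
}

#' Generate an external validation set from the same ground truth
#'
#' Builds mixtures involving chemicals \emph{not} present in the modelling
#' dataset (new descriptor vectors drawn from the same distributions,
#' optionally shifted outside the training ranges) while keeping the
#' response law of the original spec.  With zero new chemicals, the
#' external set reuses existing chemicals at temperatures halfway between
#' the original grid points.
#'
#' @param generated output of \code{\link{generate_mixture_data}}.
#' @param n_new_comp1,n_new_comp2 numbers of new chemicals per slot.
#' @param n_mixtures number of external mixtures (each contains at least
#'   one new chemical when any are requested).
#' @param shift added to the new chemicals' descriptor locations, in units
#'   of the per-descriptor scale; large values produce structural outliers
#'   (leverage beyond the threshold) downstream.
#' @param rng_seed seed (default: the spec seed + 1).
#' @return An external \code{mixture_dataset} whose component table
#'   contains both the original and the new chemicals.
#' @export
perturb_external <- function(generated, n_new_comp1 = 5, n_new_comp2 = 3,
                             n_mixtures = 30, shift = 0, rng_seed = NULL) {
  spec <- generated$truth$spec
  comp_old <- generated$dataset$components
  halide_of <- generated$truth$halide_of
  with_seed(rng_seed %||% (spec$rng_seed + 1), {
    loc <- generated$truth$descriptor_location
    scl <- generated$truth$descriptor_scale
    new1 <- if (n_new_comp1 > 0) sprintf("xHBA%02d", seq_len(n_new_comp1))
            else character(0)
    new2 <- if (n_new_comp2 > 0) sprintf("xHBD%02d", seq_len(n_new_comp2))
            else character(0)
    comp_new <- if (length(c(new1, new2))) {
      draw_components(c(new1, new2), spec$n_descriptors,
                      loc + shift * scl, scl)
    }
    components <- rbind(comp_old, comp_new)
    if (length(new1)) {
      halide_of <- c(halide_of,
                     setNames(sample(c("none", "Cl", "Br"), length(new1),
                                     replace = TRUE, prob = c(0.3, 0.5, 0.2)),
                              new1))
    }

    old1 <- unique(generated$dataset$records$comp1_id)
    old2 <- unique(generated$dataset$records$comp2_id)
    pool1 <- c(old1, new1)
    pool2 <- c(old2, new2)
    cand <- expand.grid(comp1_id = pool1, comp2_id = pool2,
                        ratio = seq_along(spec$ratios),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    if (length(c(new1, new2))) {
      cand <- cand[cand$comp1_id %in% new1 | cand$comp2_id %in% new2, ,
                   drop = FALSE]
    }
    pairs <- cand[sample.int(nrow(cand), min(n_mixtures, nrow(cand))), ,
                  drop = FALSE]
    temps_fixed <- if (!length(c(new1, new2))) {
      # unseen temperatures: midpoints of the original grid
      head(spec$temperatures_K, -1) + diff(spec$temperatures_K) / 2
    }
    records <- attach_halides(build_records(pairs, spec, temps_fixed,
                                            id_prefix = "X"),
                              halide_of)
    records$y <- synthetic_response(records, components, spec)
    mixture_dataset(records, components)
  })
}
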