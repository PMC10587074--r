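#' Configuration for the synthetic SAR generator
#'
#' Describes a synthetic activity class whose statistical shape mimics
#' curated ChEMBL-style benchmark classes: a unimodal pIC50 distribution with
#' its median in the 7--8 interval and the majority of compounds at
#' intermediate potency, analogue-series structure expressed through shared
#' fingerprint core bits, and a learnable fingerprint-to-potency mapping with
#' additive noise.
#'
#' Each analogue series owns a block of `core_bits_per_series` fingerprint
#' bits set in all of its members; each compound additionally sets
#' `sub_bits_per_compound` bits drawn from a shared pool of
#' `substituent_bits` substituent bits. Series base potencies follow a
#' two-sided mixture concentrated near `base_location`: a normal core
#' `N(base_location, base_scale)` with probability `1 - tail_prob`, and with
#' probability `tail_prob` a symmetric decaying tail
#' `base_location +/- (tail_offset + Exp(tail_scale))`, so the low- and
#' high-potency bands are populated — densely near the band edges, sparsely
#' at the extremes — the way curated classes are. Compound
#' potency is its series base plus a fixed per-substituent-bit effect for
#' every set substituent bit, plus Gaussian noise, clipped to `[5, 11]`.
#'
#' @param n_series Number of analogue series.
#' @param core_bits_per_series Core (scaffold) bits owned by each series.
#' @param substituent_bits Size of the shared substituent bit pool.
#' @param total_bits Fingerprint length; must hold all core blocks plus the
#'   substituent pool.
#' @param n_compounds Compounds drawn before quota top-up.
#' @param base_location,base_scale Centre and SD of the normal core of the
#'   series base potency distribution (pIC50 scale).
#' @param tail_prob,tail_offset,tail_scale Mixture weight, inner offset and
#'   exponential scale of the two-sided tail component of the base potency
#'   distribution (pIC50 units).
#' @param substituent_effect_sd SD of per-substituent-bit potency effects
#'   (pIC50 units).
#' @param sub_bits_per_compound Substituent bits set per compound.
#' @param noise_sd SD of per-compound Gaussian noise (pIC50 units).
#' @param min_per_subrange Minimum compounds required in each potency
#'   sub-range (default 75); the generator tops up deficient sub-ranges.
#' @param seed Integer seed; identical config + seed gives identical classes.
#' @return A `synth_config` object (a validated list).
#' @export
#' @examples
#' cfg <- synth_config(n_compounds = 400, min_per_subrange = 40)
#' cls <- generate_activity_class(cfg)
synth_config <- function(n_series = 120L,
                         core_bits_per_series = 10L,
                         substituent_bits = 384L,
                         total_bits = 2048L,
                         n_compounds = 600L,
                         base_location = 7.5,
                         base_scale = 0.4,
                         tail_prob = 0.35,
                         tail_offset = 0.5,
                         tail_scale = 0.9,
                         substituent_effect_sd = 0.12,
                         sub_bits_per_compound = 6L,
                         noise_sd = 0.15,
                         min_per_subrange = 75L,
                         seed = 1L) {
  cfg <- list(
    n_series = as.integer(n_series),
    core_bits_per_series = as.integer(core_bits_per_series),
    substituent_bits = as.integer(substituent_bits),
    total_bits = as.integer(total_bits),
    n_compounds = as.integer(n_compounds),
    base_location = base_location,
    base_scale = base_scale,
    tail_prob = tail_prob,
    tail_offset = tail_offset,
    tail_scale = tail_scale,
    substituent_effect_sd = substituent_effect_sd,
    sub_bits_per_compound = as.integer(sub_bits_per_compound),
    noise_sd = noise_sd,
    min_per_subrange = as.integer(min_per_subrange),
    seed = as.integer(seed)
  )
  if (cfg$total_bits < cfg$n_series * cfg$core_bits_per_series + cfg$substituent_bits) {
    stop("total_bits must be at least n_series * core_bits_per_series + substituent_bits",
         call. = FALSE)
  }
  if (cfg$noise_sd < 0 || cfg$substituent_effect_sd < 0) {
    stop("noise_sd and substituent_effect_sd must be non-negative", call. = FALSE)
  }
  if (cfg$min_per_subrange < 0L) {
    stop("min_per_subrange must be non-negative", call. = FALSE)
  }
  if (cfg$n_series < 1L || cfg$n_compounds < 1L) {
    stop("n_series and n_compounds must be positive", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

# Sub-range band of a base potency value.
subrange_of_base <- function(x) {
  ifelse(x < 7, "LOW", ifelse(x < 9, "MID", "HIGH"))
}

# Draw series base potencies from the two-sided mixture: normal core near
# the location, symmetric decaying tail reaching the band extremes.
draw_bases <- function(cfg, n) {
  tail <- stats::runif(n) < cfg$tail_prob
  x <- numeric(n)
  x[!tail] <- stats::rnorm(sum(!tail), cfg$base_location, cfg$base_scale)
  n_tail <- sum(tail)
  if (n_tail > 0L) {
    dev <- cfg$tail_offset + stats::rexp(n_tail, rate = 1 / cfg$tail_scale)
    sign <- ifelse(stats::runif(n_tail) < 0.5, -1, 1)
    x[tail] <- cfg$base_location + sign * dev
  }
  pmin(pmax(x, 5), 11)
}

# Draw one series base potency restricted to a sub-range band, by rejection
# from the configured mixture (so top-up series keep the class shape).
draw_base_in <- function(cfg, lo, hi, max_tries = 10000L) {
  for (i in seq_len(max_tries)) {
    x <- draw_bases(cfg, 1L)
    if (x >= lo && x < hi) {
      return(x)
    }
  }
  stats::runif(1L, lo, min(hi, 11))
}

# Materialise `n` compounds from one series: fingerprint core block plus a
# random substituent subset; potency = base + substituent effects + noise.
draw_compounds <- function(cfg, series_id, base, effects, n) {
  core_start <- (series_id - 1L) * cfg$core_bits_per_series
  sub_start <- cfg$total_bits - cfg$substituent_bits
  lapply(seq_len(n), function(i) {
    subs <- sample.int(cfg$substituent_bits, cfg$sub_bits_per_compound)
    fp <- integer(cfg$total_bits)
    fp[core_start + seq_len(cfg$core_bits_per_series)] <- 1L
    fp[sub_start + subs] <- 1L
    pic50 <- base + sum(effects[subs]) + stats::rnorm(1L, 0, cfg$noise_sd)
    list(fp = fp, pic50 = pic50, series_id = series_id)
  })
}

#' Generate one synthetic activity class
#'
#' Draws an activity class from a [synth_config()]: series base potencies,
#' per-substituent-bit effects, then compounds assigned uniformly to series.
#' Potencies are clipped to the curation window `[5, 11]` (the number of
#' clipped values is recorded in the `n_clipped` attribute). If any potency
#' sub-range ends up below `min_per_subrange`, additional compounds are drawn
#' from series whose base potency lies in the deficient band, creating new
#' series (inside the fingerprint's spare bit capacity) when none exists;
#' after a bounded number of rounds a deficiency is an error naming the
#' sub-range.
#'
#' @param config A [synth_config()] object.
#' @param class_id Identifier written into the `class_id` column.
#' @param name Human-readable class name (attribute).
#' @return A tibble with columns `compound_id`, `class_id`, `smiles` (all
#'   `NA` for synthetic compounds), `pic50`, `subrange`, `series_id`, and the
#'   list-column `fingerprint`; attributes `config`, `n_clipped`.
#' @export
generate_activity_class <- function(config, class_id = "SYNTH-01",
                                    name = class_id) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  with_seed(cfg$seed, {
    max_series <- (cfg$total_bits - cfg$substituent_bits) %/% cfg$core_bits_per_series
    bases <- draw_bases(cfg, cfg$n_series)
    effects <- stats::rnorm(cfg$substituent_bits, 0, cfg$substituent_effect_sd)

    series_of <- sample.int(cfg$n_series, cfg$n_compounds, replace = TRUE)
    rows <- unlist(lapply(seq_len(cfg$n_series), function(s) {
      n_s <- sum(series_of == s)
      if (n_s == 0L) list() else draw_compounds(cfg, s, bases[s], effects, n_s)
    }), recursive = FALSE)

    # Quota top-up: add compounds from series whose base sits in the
    # deficient band until every sub-range meets min_per_subrange.
    bands <- list(LOW = c(5, 7), MID = c(7, 9), HIGH = c(9, 11 + 1e-9))
    max_rounds <- 200L
    round <- 0L
    repeat {
      pic <- pmin(pmax(vapply(rows, `[[`, numeric(1), "pic50"), 5), 11)
      counts <- table(factor(subrange_of_base(pic), levels = names(bands)))
      deficient <- names(bands)[counts < cfg$min_per_subrange]
      if (length(deficient) == 0L) {
        break
      }
      round <- round + 1L
      if (round > max_rounds) {
        stop(sprintf("cannot satisfy the %d-per-sub-range quota for sub-range %s",
                     cfg$min_per_subrange, deficient[1]), call. = FALSE)
      }
      band <- bands[[deficient[1]]]
      donors <- which(bases >= band[1] & bases < band[2])
      # keep some series diversity in topped-up bands: occasionally found a
      # new series in the band instead of reusing an existing one
      grow <- length(donors) == 0L ||
        (length(bases) < max_series && stats::runif(1L) < 0.6)
      if (grow) {
        if (length(bases) >= max_series) {
          stop(sprintf("cannot satisfy the %d-per-sub-range quota for sub-range %s: no series capacity left",
                       cfg$min_per_subrange, deficient[1]), call. = FALSE)
        }
        bases <- c(bases, draw_base_in(cfg, band[1], min(band[2], 11)))
        donors <- length(bases)
      }
      need <- cfg$min_per_subrange - counts[[deficient[1]]]
      batch <- min(need, 5L)
      donor <- donors[sample.int(length(donors), 1L)]
      rows <- c(rows, draw_compounds(cfg, donor, bases[donor], effects, batch))
    }

    pic_raw <- vapply(rows, `[[`, numeric(1), "pic50")
    n_clipped <- sum(pic_raw < 5 | pic_raw > 11)
    pic <- pmin(pmax(pic_raw, 5), 11)
    out <- tibble::tibble(
      compound_id = sprintf("%s-%05d", class_id, seq_along(rows)),
      class_id = class_id,
      smiles = NA_character_,
      pic50 = pic,
      subrange = assign_subrange(pic),
      series_id = vapply(rows, `[[`, integer(1), "series_id"),
      fingerprint = lapply(rows, `[[`, "fp")
    )
    attr(out, "config") <- cfg
    attr(out, "n_clipped") <- n_clipped
    attr(out, "name") <- name
    out
  })
}

#' Generate a suite of synthetic activity classes
#'
#' Draws `n_classes` classes with perturbed per-class base potency locations
#' (distinct distribution peaks, as real benchmark classes show
#' class-dependent potency distributions) while keeping every class median in
#' the 7--8 interval. Each class gets its own derived seed.
#'
#' @param n_classes Number of classes (>= 1).
#' @param base_config A [synth_config()]; per-class configs perturb its
#'   `base_location`.
#' @param seed Master seed for the suite.
#' @param location_spread Half-width of the evenly spaced per-class location
#'   offsets (default 0.25 pIC50 units).
#' @return A single tibble of all classes, distinguished by `class_id`;
#'   attribute `configs` holds the per-class configs.
#' @export
#' @examples
#' suite <- generate_benchmark_suite(3, synth_config(n_compounds = 400), seed = 11)
#' dplyr::count(suite, class_id)
generate_benchmark_suite <- function(n_classes, base_config = synth_config(),
                                     seed = base_config$seed,
                                     location_spread = 0.25) {
  stopifnot(n_classes >= 1L)
  offsets <- if (n_classes == 1L) 0 else seq(-location_spread, location_spread,
                                             length.out = n_classes)
  classes <- lapply(seq_len(n_classes), function(k) {
    cfg <- base_config
    cfg$base_location <- base_config$base_location + offsets[k]
    cfg$seed <- derive_seed(seed, "synthetic-class", k)
    cid <- sprintf("SYNTH-%02d", k)
    generate_activity_class(cfg, class_id = cid, name = cid)
  })
  out <- dplyr::bind_rows(classes)
  attr(out, "configs") <- lapply(classes, attr, "config")
  out
}
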