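# Seeded generators for the three input kinds the analysis stages consume:
# triplicate logistic OD680 growth curves across treatments, FAME
# compositions perturbed around a base profile, and harvest-record series.
# All generators are pure functions of (spec, seed).

# Counter-based stream seeding: each treatment gets its own RNG stream
# derived from the global seed and its index, so adding a treatment does not
# shift the draws of the others.  Constants are the classic Lehmer
# multipliers; the modulus keeps the result a valid 32-bit seed.
.stream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 +
                as.numeric(stream) * 16807) %% 2147483647)
}

#' Specify a multi-treatment logistic growth simulation
#'
#' Defaults mirror a 15-day bottle experiment sampled every 3 days with
#' three biological replicates.
#'
#' @param treatments Named list; each element a list with logistic
#'   parameters `K` (carrying capacity, OD units), `r` (growth rate, per
#'   day) and `od0` (initial OD).
#' @param noise_sd Gaussian measurement noise sd, OD units.
#' @param replicates Biological replicates per treatment.
#' @param times Sampling times, days.
#' @param seed Integer seed.
#' @return A `growth_sim_spec` object.
#' @export
growth_sim_spec <- function(treatments, noise_sd = 0.02, replicates = 3,
                            times = seq(0, 15, by = 3), seed = 1L) {
  if (length(treatments) == 0L || is.null(names(treatments)) ||
      any(!nzchar(names(treatments)))) {
    .fame_error("treatments must be a non-empty named list",
                "famefuel_value_error")
  }
  for (nm in names(treatments)) {
    tr <- treatments[[nm]]
    if (!all(c("K", "r", "od0") %in% names(tr))) {
      .fame_error(sprintf("treatment '%s' needs K, r and od0", nm),
                  "famefuel_value_error")
    }
    if (tr$od0 <= 0 || tr$K <= tr$od0 || tr$r < 0) {
      .fame_error(sprintf(
        "treatment '%s': require K > od0 > 0 and r >= 0", nm),
        "famefuel_value_error")
    }
  }
  if (noise_sd < 0 || replicates < 1 || length(times) == 0 ||
      any(times < 0)) {
    .fame_error("invalid noise sd, replicate count or sampling times",
                "famefuel_value_error")
  }
  structure(list(treatments = treatments, noise_sd = noise_sd,
                 replicates = as.integer(replicates), times = times,
                 seed = as.integer(seed)),
            class = "growth_sim_spec")
}

#' Logistic OD680 trajectory
#'
#' OD(t) = K od0 e^(rt) / (K + od0 (e^(rt) - 1)).
#'
#' @param t Time, days (vectorized).
#' @param K Carrying capacity, OD units.
#' @param r Growth rate, per day.
#' @param od0 Initial OD.
#' @return OD680 values.
#' @export
logistic_od <- function(t, K, r, od0) {
  e <- exp(r * t)
  K * od0 * e / (K + od0 * (e - 1))
}

#' Simulate OD680 growth curves
#'
#' Each treatment's replicates follow its logistic trajectory plus Gaussian
#' measurement noise, truncated at zero (absorbances are non-negative).
#' Identical spec and seed give identical output, treatment by treatment.
#'
#' @param spec A `growth_sim_spec`.
#' @return Growth table: data frame with columns `treatment`, `time`,
#'   `replicate`, `od680`.
#'
#' @examples
#' spec <- growth_sim_spec(list(ctrl = list(K = 1, r = 0.5, od0 = 0.05)),
#'                         noise_sd = 0)
#' simulate_growth(spec)
#' @export
simulate_growth <- function(spec) {
  stopifnot(inherits(spec, "growth_sim_spec"))
  out <- lapply(seq_along(spec$treatments), function(k) {
    nm <- names(spec$treatments)[k]
    tr <- spec$treatments[[k]]
    mu <- logistic_od(spec$times, tr$K, tr$r, tr$od0)
    n <- length(spec$times) * spec$replicates
    noise <- if (spec$noise_sd > 0) {
      set.seed(.stream_seed(spec$seed, k))
      stats::rnorm(n, 0, spec$noise_sd)
    } else rep(0, n)
    data.frame(
      treatment = nm,
      time = rep(spec$times, times = spec$replicates),
      replicate = rep(seq_len(spec$replicates), each = length(spec$times)),
      od680 = pmax(0, rep(mu, times = spec$replicates) + noise),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate a FAME composition around a base profile
#'
#' Draws a Dirichlet-type perturbation of the base composition: per-species
#' gamma variates with shape `concentration` times the base fraction,
#' normalized and rescaled to the base profile's total weight percent.  The
#' species set is preserved and the expected composition equals the base;
#' larger `concentration` means a tighter draw.
#'
#' @param base A `fame_profile` to perturb (e.g. the packaged Table 2 PW
#'   profile).
#' @param concentration Dirichlet concentration parameter (> 0).
#' @param seed Integer seed.
#' @param sample_id Identifier for the simulated profile.
#' @return A `fame_profile`.
#' @export
simulate_fame <- function(base, concentration = 200, seed = 1L,
                          sample_id = paste0(base$sample_id, "_sim")) {
  stopifnot(inherits(base, "fame_profile"))
  if (nrow(base$species) == 0L) {
    .fame_error("cannot perturb an empty base profile",
                "famefuel_value_error")
  }
  if (concentration <= 0) {
    .fame_error("concentration must be positive", "famefuel_value_error")
  }
  wt <- base$species$weight_percent
  total <- sum(wt)
  set.seed(.stream_seed(seed, 0L))
  g <- stats::rgamma(length(wt), shape = concentration * wt / total, rate = 1)
  new_wt <- g / sum(g) * total
  species <- Map(parse_fame_notation, base$species$notation, new_wt)
  fame_profile(sample_id, unname(species), medium = base$medium)
}

#' Simulate harvest records from a growth series
#'
#' Converts one treatment's OD680 series into replicate harvest records via
#' a linear OD-to-dry-weight factor: each replicate's dried pellet weight is
#' OD x od_to_dw x sampled volume.  With a noiseless series, feeding the
#' result to [cultivation_summary()] recovers the programmed productivity
#' exactly.
#'
#' @param growth Growth table for a single treatment.
#' @param od_to_dw Dry weight per OD unit, g/L per OD (> 0).
#' @param sample_volume_l Volume withdrawn per replicate, L.
#' @return Harvest table: data frame with columns `time`, `replicate`,
#'   `weight_g`, `volume_l`.
#' @export
simulate_cultivation <- function(growth, od_to_dw, sample_volume_l = 0.005) {
  validate_growth_data(growth)
  if (length(unique(growth$treatment)) != 1L) {
    .fame_error("harvest simulation expects a single treatment",
                "famefuel_value_error")
  }
  if (od_to_dw <= 0 || sample_volume_l <= 0) {
    .fame_error("od_to_dw and sample volume must be positive",
                "famefuel_value_error")
  }
  data.frame(time = growth$time, replicate = growth$replicate,
             weight_g = growth$od680 * od_to_dw * sample_volume_l,
             volume_l = sample_volume_l, stringsAsFactors = FALSE)
}
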