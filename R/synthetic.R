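# run expr with a local RNG stream; the caller's global random state is
# saved and restored, so every generator is reproducible and side-effect
# free
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# derive a distinct 31-bit sub-seed; arithmetic in double to avoid integer
# overflow for large master seeds
.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(k) * 7919) %%
               2147483629)
}

#' Generate a synthetic reference EI spectrum
#'
#' Draws `n_peaks` distinct nominal masses from `[26, max_mz]` with the
#' molecular ion always present at `max_mz`, and assigns intensities by a
#' geometric decay over a randomly permuted peak rank — the simplest model
#' that yields base-peak-dominated, fragment-rich spectra of the kind EI
#' libraries hold. Purely statistical; no fragmentation chemistry is
#' implied. Deterministic for a fixed seed.
#'
#' @param n_peaks number of peaks (>= 1).
#' @param max_mz nominal molecular-ion mass; must allow `n_peaks` distinct
#'   masses in `[26, max_mz]`.
#' @param intensity_decay geometric ratio in (0, 1] between successive
#'   intensity ranks (default 0.75).
#' @param seed integer seed.
#' @param name spectrum name recorded in metadata.
#' @return A base-peak-normalized [spectrum()] object.
#' @export
gen_reference <- function(n_peaks = 20, max_mz = 130,
                          intensity_decay = 0.75, seed = 1,
                          name = "synthetic reference") {
  if (n_peaks < 1) stop("n_peaks must be >= 1", call. = FALSE)
  if (max_mz - 26 + 1 < n_peaks || max_mz <= 26)
    stop("max_mz too small for n_peaks distinct masses >= 26",
         call. = FALSE)
  if (intensity_decay <= 0 || intensity_decay > 1)
    stop("intensity_decay must be in (0, 1]", call. = FALSE)
  .with_seed(seed, {
    mz <- c(max_mz,
            sample(26:(max_mz - 1), n_peaks - 1, replace = FALSE))
    rank <- sample.int(n_peaks)  # which peak gets which intensity rank
    intensity <- intensity_decay^(rank - 1)
    normalize_base_peak(
      spectrum(mz, intensity, meta = list(name = name, mw = max_mz)))
  })
}

#' Perturb a reference spectrum with prediction-style errors
#'
#' Applies, in order, the characteristic error modes of in silico EI
#' spectrum prediction: random peak loss (`p_drop`, with `high_mass_bias`
#' extra loss probability for top-quartile m/z peaks — predictions tend to
#' miss high-mass fragments), molecular-ion inflation (`mol_ion_boost`;
#' when > 1 the molecular ion is never dropped), injection of
#' hydrogen-loss peaks at `[M-1]..[M-4]` with intensity `h_loss_intensity`,
#' and multiplicative log-normal intensity jitter (`intensity_noise` as
#' sigma on the log scale). If a draw deletes every peak it is retried
#' with a fresh substream, erroring after 100 attempts.
#'
#' @param ref reference [spectrum()]; its maximum m/z is taken as the
#'   molecular ion.
#' @param p_drop per-peak drop probability in `[0, 1]`.
#' @param mol_ion_boost multiplicative molecular-ion inflation (>= 1).
#' @param h_loss_intensity intensity added at `[M-1]..[M-4]` (0 disables).
#' @param high_mass_bias additional drop probability for top-quartile m/z
#'   peaks.
#' @param intensity_noise log-normal sigma (>= 0).
#' @param seed integer seed.
#' @return A perturbed [spectrum()] object ("the prediction").
#' @export
perturb_spectrum <- function(ref, p_drop = 0.5, mol_ion_boost = 3,
                             h_loss_intensity = 150, high_mass_bias = 0.3,
                             intensity_noise = 0.4, seed = 1) {
  stopifnot(is_spectrum(ref))
  if (p_drop < 0 || p_drop > 1 || high_mass_bias < 0 || high_mass_bias > 1)
    stop("drop probabilities must be in [0, 1]", call. = FALSE)
  if (mol_ion_boost < 1) stop("mol_ion_boost must be >= 1", call. = FALSE)
  if (intensity_noise < 0) stop("intensity_noise must be >= 0", call. = FALSE)
  mol_mz <- max(ref$mz)
  q3 <- stats::quantile(ref$mz, 0.75, names = FALSE)
  for (attempt in seq_len(100L)) {
    out <- .with_seed(.sub_seed(seed, attempt), {
      p <- rep(p_drop, length(ref$mz))
      p[ref$mz >= q3] <- pmin(1, p[ref$mz >= q3] + high_mass_bias)
      if (mol_ion_boost > 1) p[ref$mz == mol_mz] <- 0
      keep <- stats::runif(length(p)) >= p
      mz <- ref$mz[keep]
      intensity <- ref$intensity[keep]
      if (mol_ion_boost > 1 && any(mz == mol_mz))
        intensity[mz == mol_mz] <- intensity[mz == mol_mz] * mol_ion_boost
      if (h_loss_intensity > 0 && mol_mz > 5) {
        mz <- c(mz, mol_mz - 1:4)
        intensity <- c(intensity, rep(h_loss_intensity, 4L))
      }
      if (length(mz) == 0L || !any(intensity > 0)) NULL
      else {
        if (intensity_noise > 0)
          intensity <- intensity *
            exp(stats::rnorm(length(intensity), 0, intensity_noise))
        spectrum(mz, intensity,
                 meta = c(ref$meta, list(perturbed = TRUE)))
      }
    })
    if (!is.null(out)) return(out)
  }
  stop("perturbation left an empty spectrum after 100 retries",
       call. = FALSE)
}

#' Generate a trajectory ensemble from fragmentation channels
#'
#' Fixture factory for the spectrum assembler: given a list of channels
#' (each a mass partition of the parent with per-fragment IPs) and the
#' number of trajectories following each channel, emits an ensemble with
#' unique trajectory ids in a seed-shuffled order. Assembly of the result
#' is invariant to that order.
#'
#' @param channels list of `list(mass = <int vector>, ip = <numeric>)`.
#' @param n_events integer vector, events per channel.
#' @param parent_mass nominal parent ion mass; every channel's mass total
#'   must not exceed it.
#' @param seed integer seed (controls only the event order).
#' @param ... bookkeeping labels for [trajectory_ensemble()].
#' @return An `eims_ensemble` object.
#' @export
gen_ensemble <- function(channels, n_events, parent_mass, seed = 1, ...) {
  stopifnot(length(channels) == length(n_events), all(n_events >= 0))
  tot <- vapply(channels, function(ch) sum(ch$mass), numeric(1))
  if (any(tot > parent_mass))
    stop("channel mass partition exceeds parent mass", call. = FALSE)
  idx <- rep(seq_along(channels), times = n_events)
  if (length(idx) == 0L)
    stop("ensemble must contain at least one event", call. = FALSE)
  idx <- .with_seed(seed, sample(idx))
  events <- lapply(seq_along(idx), function(k) {
    ch <- channels[[idx[k]]]
    fragment_event(sprintf("traj%05d", k), ch$mass, ch$ip)
  })
  trajectory_ensemble(events, parent_mass, ...)
}

#' Hand-encoded molecular-graph fixtures
#'
#' Returns named [molecule_graph()] objects for the small molecules used
#' throughout the descriptor examples: 2-nonene, 1,8-nonadiene, furan,
#' adamantane, n-butane, n-hexane, cyclohexane and N-methylacetamide.
#'
#' @return Named list of `eims_molgraph` objects.
#' @examples
#' rotatable_bond_count(fixture_molecules()[["2-nonene"]])  # 5
#' @export
fixture_molecules <- function() {
  chain <- function(n, dbl = integer(), name) {
    o <- rep(1L, n - 1L)
    o[dbl] <- 2L
    molecule_graph(rep("C", n),
                   data.frame(i = 1:(n - 1), j = 2:n, order = o),
                   name = name)
  }
  # adamantane: 4 methine carbons (1-4) bridged pairwise by 6 methylenes
  ad_pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  ad_bonds <- do.call(rbind, lapply(1:6, function(k)
    data.frame(i = c(ad_pairs[k, 1], 4 + k),
               j = c(4 + k, ad_pairs[k, 2]), order = 1L)))
  list(
    "2-nonene" = chain(9, dbl = 2L, name = "2-nonene"),
    "1,8-nonadiene" = chain(9, dbl = c(1L, 8L), name = "1,8-nonadiene"),
    "furan" = molecule_graph(
      c("C", "C", "C", "C", "O"),
      data.frame(i = 1:5, j = c(2:5, 1), order = 4L), name = "furan"),
    "adamantane" = molecule_graph(rep("C", 10), ad_bonds,
                                  name = "adamantane"),
    "n-butane" = chain(4, name = "n-butane"),
    "n-hexane" = chain(6, name = "n-hexane"),
    "cyclohexane" = molecule_graph(
      rep("C", 6), data.frame(i = 1:6, j = c(2:6, 1), order = 1L),
      name = "cyclohexane"),
    # CH3-C(=O)-NH-CH3: atoms C1, C2(carbonyl), O, N, C3
    "N-methylacetamide" = molecule_graph(
      c("C", "C", "O", "N", "C"),
      data.frame(i = c(1, 2, 2, 4), j = c(2, 3, 4, 5),
                 order = c(1L, 2L, 1L, 1L)),
      name = "N-methylacetamide")
  )
}

#' Generate a paired reference/prediction set
#'
#' Convenience wrapper producing `n` reference spectra and their perturbed
#' predictions, each pair from an independent seeded substream.
#'
#' @param n number of pairs.
#' @param seed master seed; pair k uses substreams derived from it.
#' @param n_peaks,max_mz,intensity_decay reference generator parameters,
#'   see [gen_reference()].
#' @param ... perturbation parameters passed to [perturb_spectrum()].
#' @return List of `n` elements, each `list(id, ref, pred)`.
#' @export
gen_pairs <- function(n, seed = 1, n_peaks = 20, max_mz = 130,
                      intensity_decay = 0.75, ...) {
  lapply(seq_len(n), function(k) {
    ref <- gen_reference(n_peaks = n_peaks, max_mz = max_mz,
                         intensity_decay = intensity_decay,
                         seed = .sub_seed(seed, 2L * k),
                         name = sprintf("pair%04d", k))
    pred <- perturb_spectrum(ref, seed = .sub_seed(seed, 2L * k + 1L), ...)
    list(id = sprintf("pair%04d", k), ref = ref, pred = pred)
  })
}
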