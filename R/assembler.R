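#' Fragmentation event and trajectory ensemble containers
#'
#' A fragment event records the final fragments of one fragmentation
#' trajectory of an ionized molecule: nominal masses, optional formulas and
#' vertical ionization potentials (IPs). An ensemble collects the events of
#' many independent trajectories for one parent ion, together with the
#' bookkeeping parameters of the simulation that produced them (number of
#' trajectories `ntraj`, impact excess energy per atom `ieeatm` in eV,
#' initial temperature `tinit` in K) — carried as labels only, no dynamics
#' is computed here.
#'
#' @param trajectory_id scalar identifier, unique within an ensemble.
#' @param mass positive integer nominal masses (Da) of the fragments.
#' @param ip vertical ionization potentials (eV), all > 0.
#' @param formula optional character vector of fragment formulas.
#' @param max_fragments cap on fragments per trajectory (default 3, the
#'   conventional per-trajectory fragment limit).
#' @return `fragment_event()`: object of class `eims_event`.
#' @export
fragment_event <- function(trajectory_id, mass, ip, formula = NULL,
                           max_fragments = 3L) {
  if (length(mass) < 1L || length(mass) > max_fragments)
    stop("event must have between 1 and ", max_fragments, " fragments",
         call. = FALSE)
  if (length(ip) != length(mass))
    stop("mass and ip must have equal length", call. = FALSE)
  if (any(mass <= 0) || any(mass != round(mass)))
    stop("fragment masses must be positive integers", call. = FALSE)
  if (any(ip <= 0)) stop("ionization potentials must be > 0", call. = FALSE)
  structure(list(trajectory_id = trajectory_id,
                 mass = as.integer(mass), ip = as.numeric(ip),
                 formula = formula),
            class = "eims_event")
}

#' @rdname fragment_event
#' @param events list of `eims_event` objects with unique trajectory ids.
#' @param parent_mass nominal mass (Da) of the intact molecular ion; every
#'   event's total fragment mass must not exceed it.
#' @param ntraj,ieeatm,tinit simulation bookkeeping labels (see above).
#' @return `trajectory_ensemble()`: object of class `eims_ensemble`.
#' @export
trajectory_ensemble <- function(events, parent_mass,
                                ntraj = NULL, ieeatm = 0.6, tinit = 500) {
  stopifnot(is.list(events),
            all(vapply(events, inherits, logical(1), "eims_event")))
  if (length(events) == 0L)
    stop("ensemble must contain at least one event", call. = FALSE)
  ids <- vapply(events, function(e) as.character(e$trajectory_id),
                character(1))
  if (anyDuplicated(ids))
    stop("trajectory ids must be unique", call. = FALSE)
  tot <- vapply(events, function(e) sum(e$mass), numeric(1))
  if (any(tot > parent_mass))
    stop("event fragment masses exceed the parent mass", call. = FALSE)
  structure(list(events = events, parent_mass = as.integer(parent_mass),
                 config = list(ntraj = ntraj, ieeatm = ieeatm,
                               tinit = tinit)),
            class = "eims_ensemble")
}

#' @export
print.eims_ensemble <- function(x, ...) {
  cat("Trajectory ensemble:", length(x$events), "events, parent mass",
      x$parent_mass, "Da\n")
  invisible(x)
}

#' Assign the charge among the fragments of one event
#'
#' Implements Stevenson's rule: upon fragmentation the fragment with the
#' lower ionization energy preferentially retains the charge. The default
#' `lowest_ip` rule is deterministic — weight 1 on the minimum-IP fragment,
#' ties split equally. The `boltzmann` rule softens this to
#' `w_i ∝ exp(-(ip_i - min ip) / kT)` with an electronic temperature
#' parameter `kT` in eV; as `kT → 0` it converges to `lowest_ip`.
#'
#' @param event an [fragment_event()] object.
#' @param rule `"lowest_ip"` (default) or `"boltzmann"`.
#' @param kT electronic temperature in eV for the Boltzmann rule (> 0).
#' @return Numeric charge weights, one per fragment, summing to 1.
#' @examples
#' e <- fragment_event("t1", mass = c(54, 28), ip = c(9.0, 14.0))
#' assign_charge(e)  # c(1, 0): the low-IP fragment keeps the charge
#' @export
assign_charge <- function(event, rule = c("lowest_ip", "boltzmann"),
                          kT = 0.1) {
  stopifnot(inherits(event, "eims_event"))
  rule <- match.arg(rule)
  ip <- event$ip
  if (rule == "lowest_ip") {
    w <- as.numeric(ip == min(ip))
  } else {
    if (kT <= 0) stop("kT must be > 0 for the boltzmann rule", call. = FALSE)
    w <- exp(-(ip - min(ip)) / kT)
  }
  w / sum(w)
}

#' Assemble a consensus spectrum from a trajectory ensemble
#'
#' Each trajectory contributes its charge weights at the nominal masses of
#' its fragments; fragments that stay neutral (weight 0 under the
#' deterministic rule) contribute nothing, and equal-mass ions from
#' different formulas accumulate into one peak. The pre-normalization total
#' intensity therefore equals the number of events (each event carries
#' exactly one charge). The result is base-peak normalized and is a pure
#' function of the ensemble and configuration: repeated calls are
#' identical.
#'
#' @param ens an [trajectory_ensemble()] object.
#' @param rule,kT charge assignment, see [assign_charge()].
#' @param scale base-peak normalization target, default 999.
#' @return An [spectrum()] object.
#' @export
assemble_spectrum <- function(ens, rule = c("lowest_ip", "boltzmann"),
                              kT = 0.1, scale = 999) {
  stopifnot(inherits(ens, "eims_ensemble"))
  rule <- match.arg(rule)
  mass <- unlist(lapply(ens$events, `[[`, "mass"))
  w <- unlist(lapply(ens$events, assign_charge, rule = rule, kT = kT))
  keep <- w > 0
  if (!any(keep))
    stop("no charged fragments to assemble", call. = FALSE)
  s <- spectrum(mass[keep], w[keep],
                meta = list(mw = ens$parent_mass,
                            config = ens$config))
  normalize_base_peak(s, scale = scale)
}

#' Default trajectory count for a molecule
#'
#' The conventional default number of fragmentation trajectories: 25 per
#' atom (hydrogens included).
#'
#' @param n_atoms positive integer total atom count.
#' @return `25 * n_atoms`.
#' @export
default_ntraj <- function(n_atoms) {
  if (length(n_atoms) != 1L || n_atoms < 1 || n_atoms != round(n_atoms))
    stop("n_atoms must be a positive integer", call. = FALSE)
  as.integer(25L * n_atoms)
}

#' Read a trajectory event table
#'
#' Reads a CSV with columns `traj_id`, `frag_index`, `nominal_mass`,
#' optional `formula`, `ip_ev`, groups rows into events by trajectory, and
#' validates the ensemble invariants.
#'
#' @param path CSV file path.
#' @param parent_mass nominal molecular-ion mass (Da); defaults to the
#'   largest per-trajectory mass total in the table.
#' @param max_fragments per-trajectory fragment cap (default 3).
#' @param ... bookkeeping labels passed to [trajectory_ensemble()].
#' @return An `eims_ensemble` object.
#' @export
read_events <- function(path, parent_mass = NULL, max_fragments = 3L, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("traj_id", "frag_index", "nominal_mass", "ip_ev")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("event table format error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L)
    stop("event table is empty", call. = FALSE)
  if (!is.numeric(df$nominal_mass) || !is.numeric(df$ip_ev) ||
      !is.numeric(df$frag_index))
    stop("event table format error: non-numeric mass/ip/index column",
         call. = FALSE)
  if (anyDuplicated(df[c("traj_id", "frag_index")]))
    stop("event table integrity error: duplicate (traj_id, frag_index)",
         call. = FALSE)
  split_idx <- split(seq_len(nrow(df)), df$traj_id)
  # preserve first-appearance order of trajectories
  split_idx <- split_idx[unique(as.character(df$traj_id))]
  events <- lapply(names(split_idx), function(id) {
    rows <- df[split_idx[[id]], ]
    rows <- rows[order(rows$frag_index), ]
    if (nrow(rows) > max_fragments)
      stop("event table integrity error: trajectory '", id, "' has ",
           nrow(rows), " fragments (max ", max_fragments, ")",
           call. = FALSE)
    fragment_event(id, rows$nominal_mass, rows$ip_ev,
                   formula = if ("formula" %in% names(rows)) rows$formula,
                   max_fragments = max_fragments)
  })
  if (is.null(parent_mass))
    parent_mass <- max(vapply(events, function(e) sum(e$mass), numeric(1)))
  trajectory_ensemble(events, parent_mass, ...)
}
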