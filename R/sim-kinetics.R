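#' Kinetic parameters of one gene
#'
#' The simulator's transcription-unit model: polymerases initiate as a Poisson
#' process at `initiation_rate` (events/minute) and elongate at a
#' piecewise-constant velocity over gene-body position. A scalar `velocity`
#' describes a single piece covering the whole body; a vector of velocities
#' with matching `segment_ends` (bp offsets from the TSS, last equal to the
#' gene length at simulation time) describes a position-dependent profile.
#'
#' @param initiation_rate Polymerases per minute, >= 0 (default 2, typical of an actively transcribed gene).
#' @param velocity Elongation velocity per segment, kb/minute, all > 0.
#' @param segment_ends Right bp boundary of each velocity segment (NULL for a
#'   single segment spanning the gene).
#' @return A `kinetics_spec` list.
#' @export
kinetics_spec <- function(initiation_rate = 2, velocity = 2, segment_ends = NULL) {
  assert_scalar_number(initiation_rate, "initiation_rate", nonneg = TRUE)
  if (!is.numeric(velocity) || length(velocity) < 1 || any(!is.finite(velocity)) ||
      any(velocity <= 0)) {
    abort_velo("all velocity pieces must be finite and > 0")
  }
  if (!is.null(segment_ends)) {
    if (length(segment_ends) != length(velocity)) {
      abort_velo("`segment_ends` must have one entry per velocity piece")
    }
    if (any(diff(c(0, segment_ends)) <= 0)) {
      abort_velo("`segment_ends` must be strictly increasing from 0")
    }
  } else if (length(velocity) != 1) {
    abort_velo("`segment_ends` is required when `velocity` has several pieces")
  }
  structure(list(initiation_rate = initiation_rate,
                 velocity = velocity,
                 segment_ends = segment_ends),
            class = "kinetics_spec")
}

#' Experimental-condition specification
#'
#' Models acute perturbation (e.g. degron-mediated depletion of an elongation
#' factor) as a global multiplicative change in elongation velocity: for
#' t >= `onset_time` every velocity piece is multiplied by `velocity_factor`.
#' The control condition has factor 1.
#'
#' @param name Condition name.
#' @param velocity_factor Dimensionless multiplier, > 0.
#' @param onset_time Minutes; time at which the factor takes effect.
#' @return A `condition_spec` list.
#' @export
condition_spec <- function(name, velocity_factor = 1, onset_time = 0) {
  assert_scalar_number(velocity_factor, "velocity_factor", positive = TRUE)
  assert_scalar_number(onset_time, "onset_time")
  structure(list(name = as.character(name),
                 velocity_factor = velocity_factor,
                 onset_time = onset_time),
            class = "condition_spec")
}

#' Sequencing-design specification for the simulator
#'
#' Defines the metabolic-labeling window and the sequencing capture rates of
#' each assay. Depths are rates, constant across conditions within a sample
#' (so global occupancy shifts are visible, as with spike-in-anchored real
#' libraries): `ttseq_depth` is expected fragments per kb of 4sU-labeled RNA,
#' `mnet_depth` expected reads per engaged polymerase, and `chip_signal` /
#' `chip_background` expected fragments per kb of gene body /
#' genome. Per-sample library depth differences are modeled by a
#' dimensionless `library_scale` multiplier applied at emission time.
#'
#' @param label_start Minutes; start of the 4sU pulse (default 60, i.e. one
#'   hour after perturbation onset).
#' @param label_duration Minutes; pulse length (default 5).
#' @param ttseq_depth Expected TT-seq fragments per kb of labeled RNA.
#' @param mnet_depth Expected mNET-seq reads per engaged polymerase.
#' @param chip_signal Expected ChIP signal fragments per kb of gene body.
#' @param chip_background Expected ChIP background fragments per kb of genome.
#' @param fragment_length Two integers, min/max fragment length (bp).
#' @param spike_leakage Fraction of an unlabeled spike-in's expected count
#'   that leaks through 4sU selection (default 0).
#' @return A `sampling_spec` list with derived `sample_time`.
#' @export
sampling_spec <- function(label_start = 60, label_duration = 5,
                          ttseq_depth = 2, mnet_depth = 40,
                          chip_signal = 2, chip_background = 20,
                          fragment_length = c(150L, 300L),
                          spike_leakage = 0) {
  assert_scalar_number(label_duration, "label_duration", positive = TRUE)
  assert_scalar_number(label_start, "label_start")
  for (nm in c("ttseq_depth", "mnet_depth", "chip_signal", "chip_background")) {
    assert_scalar_number(get(nm), nm, nonneg = TRUE)
  }
  if (length(fragment_length) != 2 || fragment_length[1] > fragment_length[2] ||
      fragment_length[1] < 1) {
    abort_velo("`fragment_length` must be c(min, max) with 1 <= min <= max")
  }
  if (spike_leakage < 0 || spike_leakage > 1) {
    abort_velo("`spike_leakage` must be in [0, 1]")
  }
  structure(list(label_start = label_start, label_duration = label_duration,
                 sample_time = label_start + label_duration,
                 ttseq_depth = ttseq_depth, mnet_depth = mnet_depth,
                 chip_signal = chip_signal, chip_background = chip_background,
                 fragment_length = as.integer(fragment_length),
                 spike_leakage = spike_leakage),
            class = "sampling_spec")
}

# velocity pieces in bp/min with bp boundaries clipped/extended to gene length
.velocity_pieces <- function(kin, gene_length) {
  ends <- kin$segment_ends %||% gene_length
  ends[length(ends)] <- gene_length
  list(bounds = c(0, ends), v = kin$velocity * 1000)
}

# Vectorized piecewise-linear advance: start positions p0 (bp), time budgets
# dt (min), piece boundaries and velocities (bp/min). Positions cap at the
# last boundary (gene end).
.advance <- function(p0, dt, bounds, v) {
  p <- pmin(pmax(p0, 0), bounds[length(bounds)])
  rem <- pmax(dt, 0)
  for (k in seq_along(v)) {
    lo <- bounds[k]; hi <- bounds[k + 1]
    inside <- p >= lo & p < hi & rem > 0
    if (!any(inside)) next
    move <- ifelse(inside, pmin(hi - p, rem * v[k]), 0)
    p <- p + move
    rem <- rem - move / v[k]
  }
  p
}

# Position of each trajectory at time t (bp offset from TSS). NA for
# trajectories that have not initiated by t.
.positions_at <- function(init_time, t, gene_length, kin, cond) {
  pieces <- .velocity_pieces(kin, gene_length)
  onset <- cond$onset_time
  f <- cond$velocity_factor
  # pre-onset phase at base velocity
  dt_old <- pmax(0, pmin(t, onset) - init_time)
  p <- .advance(rep(0, length(init_time)), dt_old, pieces$bounds, pieces$v)
  # post-onset phase at scaled velocity
  dt_new <- pmax(0, t - pmax(init_time, onset))
  p <- .advance(p, dt_new, pieces$bounds, pieces$v * f)
  p[init_time > t] <- NA_real_
  p
}

#' Simulate Pol II initiation events and trajectories for one gene
#'
#' Initiation times are a homogeneous Poisson process at the gene's initiation
#' rate over `[-warmup, horizon]`; a warm-up interval lets occupancy reach
#' steady state before sampling. Each polymerase then moves deterministically
#' according to the kinetic spec and condition (velocity multiplied by the
#' condition factor from its onset time), terminating when it reaches the
#' gene end. Deterministic given `seed`.
#'
#' @param gene One-row gene tibble.
#' @param kin A [kinetics_spec()].
#' @param cond A [condition_spec()].
#' @param horizon Minutes; trajectories may initiate up to this time.
#' @param seed Integer seed (NULL to use the current RNG stream).
#' @param warmup Minutes of pre-horizon initiation (default 0).
#' @return A `pol_trajectories` tibble with column `init_time` and the gene,
#'   kinetics, condition and horizon attached as attributes.
#' @export
simulate_trajectories <- function(gene, kin, cond, horizon, seed = NULL,
                                  warmup = 0) {
  if (!inherits(kin, "kinetics_spec")) abort_velo("`kin` must be a kinetics_spec")
  if (!inherits(cond, "condition_spec")) abort_velo("`cond` must be a condition_spec")
  assert_scalar_number(horizon, "horizon", positive = TRUE)
  assert_scalar_number(warmup, "warmup", nonneg = TRUE)
  init <- with_seed(seed, {
    n <- stats::rpois(1, kin$initiation_rate * (horizon + warmup))
    sort(stats::runif(n, -warmup, horizon))
  })
  structure(tibble::tibble(init_time = init),
            gene = gene, kin = kin, cond = cond, horizon = horizon,
            class = c("pol_trajectories", class(tibble::tibble())))
}

#' Evaluate trajectory positions at a time point
#'
#' @param traj A `pol_trajectories` tibble from [simulate_trajectories()].
#' @param t Minutes.
#' @return Numeric bp offsets from the TSS (capped at gene length; NA for
#'   trajectories initiating after `t`).
#' @export
trajectory_positions <- function(traj, t) {
  gene <- attr(traj, "gene")
  L <- gene$end - gene$start
  .positions_at(traj$init_time, t, L, attr(traj, "kin"), attr(traj, "cond"))
}

# gene-body offset -> genomic base of width 1 (active site)
.offset_to_base <- function(gene, offset) {
  if (gene$strand == "+") gene$start + floor(offset) else gene$end - 1 - floor(offset)
}

#' Genomic positions of engaged polymerases (mNET-seq ground state)
#'
#' One width-1 record per polymerase that has initiated by `t` and has not yet
#' reached the gene end, at the genomic base of its active site (the last
#' incorporated nucleotide). Offset 0 maps to the TSS; minus-strand genes are
#' reflected.
#'
#' @inheritParams trajectory_positions
#' @param sample Sample label for the emitted records.
#' @return A tag-record tibble (BED6-style columns plus `sample`).
#' @export
engaged_positions <- function(traj, t, sample = "S1") {
  gene <- attr(traj, "gene")
  L <- gene$end - gene$start
  pos <- trajectory_positions(traj, t)
  keep <- !is.na(pos) & pos < L
  if (!any(keep)) return(empty_records())
  base <- .offset_to_base(gene, pos[keep])
  as_record_tibble(gene$chrom, base, base + 1L,
                   paste0(gene$gene_id, "_pol", which(keep)),
                   gene$strand, sample)
}

#' Gene-body segments transcribed during a labeling window
#'
#' For each trajectory, the segment of nascent RNA synthesized during
#' `[t0, t1]` (positions traversed in the window), clipped to the gene body
#' and mapped to genomic coordinates. Trajectories initiating after `t1` or
#' terminated before `t0` yield nothing.
#'
#' @inheritParams trajectory_positions
#' @param window Two minutes values `c(t0, t1)`, t0 < t1.
#' @return Tibble of stranded genomic intervals (`chrom`, `start`, `end`,
#'   `strand`), one row per trajectory with nonempty labeled segment.
#' @export
labeled_intervals <- function(traj, window) {
  if (length(window) != 2 || window[1] >= window[2]) {
    abort_velo("`window` must be c(t0, t1) with t0 < t1")
  }
  gene <- attr(traj, "gene")
  L <- gene$end - gene$start
  p0 <- trajectory_positions(traj, window[1])
  p1 <- trajectory_positions(traj, window[2])
  p0[is.na(p0)] <- 0
  keep <- !is.na(p1) & p1 > p0 & p0 < L
  if (!any(keep)) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character()))
  }
  o1 <- floor(p0[keep]); o2 <- ceiling(pmin(p1[keep], L))
  if (gene$strand == "+") {
    s <- gene$start + o1; e <- gene$start + o2
  } else {
    s <- gene$end - o2; e <- gene$end - o1
  }
  tibble::tibble(chrom = gene$chrom, start = as.integer(s),
                 end = as.integer(e), strand = gene$strand)
}
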