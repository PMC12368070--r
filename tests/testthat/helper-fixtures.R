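# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except files the tests themselves write to tempdir().

toy_gene <- function(gene_id = "g1", start = 1000L, end = 61000L,
                     strand = "+", chrom = "chr1") {
  tibble::tibble(gene_id = gene_id, chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand,
                 biotype = "protein_coding")
}

# trajectories with hand-chosen initiation times (bypasses the Poisson draw)
forced_trajectories <- function(init_times, gene, kin, cond, horizon = 1e6) {
  structure(tibble::tibble(init_time = init_times),
            gene = gene, kin = kin, cond = cond, horizon = horizon,
            class = c("pol_trajectories", class(tibble::tibble())))
}

toy_records <- function(starts, ends, strands, sample = "s1", chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = as.integer(starts),
                 end = as.integer(ends),
                 name = sprintf("r%03d", seq_along(starts)), score = 0L,
                 strand = strands, sample = sample)
}

# brute-force per-base IntersectionNotEmpty oracle (independent of the
# GenomicRanges-based implementation): enumerate feature sets base by base
oracle_count <- function(records, features, ignore_strand = FALSE) {
  ids <- features$gene_id
  owner_of <- function(chrom, base, strand) {
    hit <- features$chrom == chrom & features$start <= base &
      base < features$end
    if (!ignore_strand) hit <- hit & features$strand == strand
    which(hit)
  }
  res <- list(assigned = integer(0), counts = stats::setNames(
    rep(0L, length(ids)), ids), ambiguous = 0L, unassigned = 0L)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    feats_per_base <- lapply(r$start:(r$end - 1),
                             function(b) owner_of(r$chrom, b, r$strand))
    touched <- unique(unlist(feats_per_base))
    if (length(touched) == 0) {
      res$unassigned <- res$unassigned + 1L
      next
    }
    # bases owned by exactly one feature
    uniq <- unlist(feats_per_base[vapply(feats_per_base, length, 1L) == 1])
    tgt <- unique(uniq)
    if (length(tgt) == 1) {
      res$counts[ids[tgt]] <- res$counts[ids[tgt]] + 1L
      res$assigned <- c(res$assigned, i)
    } else {
      res$ambiguous <- res$ambiguous + 1L
    }
  }
  res
}

# exact signed-rank p by enumerating all 2^n sign assignments
enum_signed_rank_p <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  v_obs <- sum(r[x > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(signs) %*% r
  p_ge <- mean(vs >= v_obs)
  p_le <- mean(vs <= v_obs)
  min(1, 2 * min(p_ge, p_le))
}

# exact rank-sum p by enumerating all choose(n1+n2, n1) group assignments
enum_rank_sum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n1 <- length(a)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  ws <- apply(combs, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(ws >= w_obs), mean(ws <= w_obs)))
}

# one steady-state two-condition dataset reused by several acceptance checks
steady_state_dataset <- function(n_genes = 200, seed = 42) {
  gn <- synthetic_genome(n_genes, c(10e3, 100e3), spacing = 20e3,
                         seed = seed + 1)
  kin <- kinetics_spec(initiation_rate = 2, velocity = 2)
  conds <- list(condition_spec("control", 1, 0),
                condition_spec("depleted", 0.5, onset_time = -1e4))
  ds <- emit_dataset(gn, kin, conds, sampling_spec(), replicates = 2,
                     assays = c("ttseq", "mnet"), seed = seed)
  list(genome = gn, ds = ds)
}

records_of <- function(ds, assay, condition) {
  ss <- ds$samples$sample[ds$samples$assay == assay &
                            ds$samples$condition == condition]
  ds$records[[assay]][ds$records[[assay]]$sample %in% ss, ]
}
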