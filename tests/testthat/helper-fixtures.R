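# Shared fixtures. Simulations are cached across test files (the suite is
# run in one process) so repeated conditions are simulated once.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

ref_genome <- function() {
  cached("genome", make_genome(40, 300000, seed = 1))
}

# full condition run on the reference genome: simulate, render, normalize
condition_run <- function(condition, seed, read_depth = 400000L) {
  key <- sprintf("run_%s_%d_%d", condition, seed, read_depth)
  cached(key, {
    ann <- ref_genome()
    bar <- derive_barriers(ann, condition)
    cfg <- simulation_config(condition = condition, seed = seed,
                             read_depth = read_depth)
    sn <- simulate_population(ann, bar, cfg)
    M <- render_contact_map(sn, ann, cfg)
    list(ann = ann, barriers = bar, config = cfg, snapshots = sn,
         map = M, map_norm = vc_sqrt_normalize(M),
         tracks = render_tracks(sn, ann, condition))
  })
}

# symmetric Poisson matrix with constant expected value (flat background)
flat_matrix <- function(n, lambda = 30, seed = 1, bin_size_bp = 1000L) {
  withr::with_seed(seed, {
    up <- matrix(0, n, n)
    iu <- upper.tri(up, diag = TRUE)
    up[iu] <- stats::rpois(sum(iu), lambda)
    M <- up + t(up)
    diag(M) <- diag(M) / 2
    contact_matrix(M, bin_size_bp = bin_size_bp, normalized = "VC_SQRT")
  })
}

# random small symmetric count matrix for oracle tests
random_matrix <- function(n, seed, bin_size_bp = 1000L) {
  withr::with_seed(seed, {
    up <- matrix(0, n, n)
    iu <- upper.tri(up, diag = TRUE)
    up[iu] <- stats::rpois(sum(iu), stats::runif(sum(iu), 1, 20))
    M <- up + t(up)
    diag(M) <- diag(M) / 2
    contact_matrix(M, bin_size_bp = bin_size_bp, normalized = "VC_SQRT")
  })
}

# random pairs table over two chromosomes
random_pairs <- function(n, seed, chroms = c("chrA", "chrB"),
                         len = 100000L) {
  withr::with_seed(seed, {
    pairs_table(data.frame(
      chrom1 = sample(chroms, n, replace = TRUE),
      pos1 = sample.int(len, n, replace = TRUE) - 1L,
      chrom2 = sample(chroms, n, replace = TRUE),
      pos2 = sample.int(len, n, replace = TRUE) - 1L
    ))
  })
}

# snapshots with static extruders planted at given bin pairs, each present
# independently per snapshot
planted_snapshots <- function(pairs, occupancy = 0.5, n_snap = 500,
                              seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n_snap), function(s) {
      sel <- stats::runif(nrow(pairs)) < occupancy
      cbind(left = pairs[sel, 1L], right = pairs[sel, 2L])
    })
  })
}

empty_snapshots <- function(n_snap = 500) {
  lapply(seq_len(n_snap), function(i) cbind(left = integer(0),
                                            right = integer(0)))
}

# ground-truth planted anchor pairs: convergent junctions two apart
planted_anchor_pairs <- function(ann = ref_genome(), min_sep_bins = 12L) {
  conv <- bin_of_bp(ann$convergent_sites, ann$bin_size_bp)
  p <- cbind(conv[seq_len(length(conv) - 2L)], conv[-(1:2)])
  p[p[, 2L] - p[, 1L] >= min_sep_bins, , drop = FALSE]
}

bin_of_bp <- function(pos, bin_size) as.integer(floor(pos / bin_size)) + 1L

# does a loop-call table contain a call near (i, j) bins (within tol bins)?
has_call_near <- function(calls, i, j, bin_size, tol = 1L) {
  any(abs(calls$anchor_up_start / bin_size + 1L - i) <= tol &
        abs(calls$anchor_down_start / bin_size + 1L - j) <= tol)
}
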