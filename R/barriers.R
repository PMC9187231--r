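#' Experimental condition presets
#'
#' The eight condition presets modelled by the simulator. Conditions alter
#' the barrier landscape (which genomic elements block extruder legs), the
#' cohesin loading rate (loader depletion) or the unloading probability
#' (unloader depletion):
#'
#' * `WT_G2M` -- G2/M arrest, transcription on: a directional barrier at
#'   every gene 3' end plus an absolute centromere barrier.
#' * `thiolutin` -- transcription inhibited: gene barriers removed, except
#'   stress-response genes, which are induced and gain strong 3'-end
#'   barriers.
#' * `scc2_depleted` -- loader depleted: barriers as WT, loading rate
#'   scaled by 0.05.
#' * `wpl1_depleted` -- unloader depleted: barriers as WT, unloading
#'   probability scaled by 0.1.
#' * `HU` -- hydroxyurea S-phase arrest: WT barriers plus absolute
#'   two-sided barriers at the stalled replication forks flanking each
#'   early-firing origin.
#' * `HU_scc2`, `HU_wpl1` -- HU arrest with loader/unloader co-depletion.
#' * `thiolutin_scc2` -- transcription inhibition after loader depletion.
#'
#' @return character vector of condition names.
#' @export
conditions <- function() {
  c("WT_G2M", "thiolutin", "scc2_depleted", "wpl1_depleted",
    "HU", "HU_scc2", "HU_wpl1", "thiolutin_scc2")
}

condition_is_hu <- function(condition) {
  condition %in% c("HU", "HU_scc2", "HU_wpl1")
}

condition_is_thiolutin <- function(condition) {
  condition %in% c("thiolutin", "thiolutin_scc2")
}

#' Rate multipliers implied by a condition preset
#'
#' Loader (Scc2) depletion scales the loading rate by 0.05 and unloader
#' (Wpl1) depletion scales the unloading probability by 0.1; depletion in
#' the cell is substantial but not complete, hence nonzero residuals.
#'
#' @param condition one of [conditions()].
#' @return list with `loading` and `unloading` multipliers.
#' @export
condition_rate_multipliers <- function(condition) {
  check_condition(condition)
  loading <- if (condition %in% c("scc2_depleted", "HU_scc2",
                                  "thiolutin_scc2")) 0.05 else 1
  unloading <- if (condition %in% c("wpl1_depleted", "HU_wpl1")) 0.1 else 1
  list(loading = loading, unloading = unloading)
}

check_condition <- function(condition) {
  if (length(condition) != 1L || !condition %in% conditions()) {
    stopf("unknown condition '%s'; must be one of: %s",
          paste(condition, collapse = ","), paste(conditions(), collapse = ", "))
  }
  invisible(condition)
}

#' Derive the loop-extrusion barrier landscape for a condition
#'
#' Transcribed genes block extruder legs that run head-on into elongating
#' polymerase, i.e. legs entering the gene through its 3' end: a `+` gene's
#' 3'-end barrier blocks left-moving legs, a `-` gene's blocks right-moving
#' legs. Barrier permeability decreases linearly with expression level and
#' reaches 0 (absolute block) at `expression_level >= permeability_scale`;
#' at that saturating expression the gene body is so loaded with
#' polymerase that co-directional passage stalls too, so absolute gene
#' barriers block both directions (as induced stress-response genes do,
#' which insulate on both sides).
#' Centromeres are absolute two-sided barriers in every condition. Under
#' transcription inhibition, gene barriers disappear except at induced
#' stress-response genes, which gain absolute 3'-end barriers. Under HU
#' arrest the two stalled forks flanking each early origin (at
#' `position +/- fork_distance_bp`) add absolute two-sided barriers.
#' Loader/unloader depletion leaves barriers unchanged (it alters rates,
#' see [condition_rate_multipliers()]).
#'
#' @param annotation a `genome_annotation`.
#' @param condition one of [conditions()].
#' @param fork_distance_bp distance from an early origin to its stalled
#'   forks; default 7500 bp, the midpoint of the 5--10 kb replicated span
#'   around early origins under HU arrest.
#' @param permeability_scale expression level at which a gene barrier
#'   becomes absolute.
#' @param max_permeability permeability of a barrier at zero expression;
#'   the default 0.05 makes even weakly transcribed genes effective
#'   barriers on the time scale of one extruder residence, which is the
#'   regime in which loops pin at adjacent convergent junctions.
#' @return a `barrier_set`: data.frame with `bin` (1-based bin index),
#'   `direction` (`"left"`, `"right"` or `"both"`: which leg movement is
#'   blocked) and `permeability` in \[0, 1\] (0 = absolute block). One row
#'   per bin; coincident barriers are merged (min permeability, directions
#'   unioned).
#' @export
derive_barriers <- function(annotation, condition,
                            fork_distance_bp = 7500,
                            permeability_scale = 2,
                            max_permeability = 0.05) {
  check_condition(condition)
  bs <- annotation$bin_size_bp
  nb <- n_bins(annotation)
  g <- annotation$genes

  bins <- integer(0); dir <- character(0); perm <- numeric(0)
  add <- function(b, d, p) {
    keep <- b >= 1L & b <= nb
    bins <<- c(bins, b[keep]); dir <<- c(dir, d[keep]); perm <<- c(perm, p[keep])
  }

  tp_bins <- bin_of(gene_three_prime_ends(g), bs)
  tp_dir <- ifelse(g$strand == "+", "left", "right")
  gene_perm <- max_permeability * pmax(0, 1 - g$expression_level / permeability_scale)
  # polymerase-saturated genes stall extruders in either direction
  tp_dir[gene_perm <= 0] <- "both"

  if (condition_is_thiolutin(condition)) {
    sel <- g$is_stress_gene
    add(tp_bins[sel], rep("both", sum(sel)), rep(0, sum(sel)))
  } else {
    add(tp_bins, tp_dir, gene_perm)
  }

  add(bin_of(annotation$centromere_bp, bs), "both", 0)

  if (condition_is_hu(condition)) {
    early <- annotation$origins$position[annotation$origins$is_early]
    fork <- c(early - fork_distance_bp, early + fork_distance_bp)
    add(bin_of(fork, bs), rep("both", length(fork)), rep(0, length(fork)))
  }

  b <- data.frame(bin = bins, direction = dir, permeability = perm,
                  stringsAsFactors = FALSE)
  b <- merge_barriers(b)
  structure(b[order(b$bin), , drop = FALSE], class = c("barrier_set", "data.frame"))
}

# collapse barriers landing in the same bin: union directions, min permeability
merge_barriers <- function(b) {
  if (nrow(b) < 2L) return(b)
  out <- lapply(split(b, b$bin), function(d) {
    dirs <- unique(d$direction)
    dir <- if ("both" %in% dirs || all(c("left", "right") %in% dirs)) {
      "both"
    } else dirs[[1L]]
    data.frame(bin = d$bin[[1L]], direction = dir,
               permeability = min(d$permeability), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Bins of absolute (permeability-0) barriers
#' @param barriers a `barrier_set`.
#' @return integer vector of bin indices.
#' @export
absolute_barrier_bins <- function(barriers) {
  sort(unique(barriers$bin[barriers$permeability <= 0]))
}
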