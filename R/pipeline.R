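#' Run the simulate-and-analyse pipeline for one condition
#'
#' End-to-end deterministic run: genome annotation, condition barrier set,
#' extrusion simulation, contact-map and track rendering, coverage-sqrt
#' normalization, insulation scoring, loop calling and cohesin-anchor
#' filtering. Returns all intermediates plus a run manifest of record
#' counts; optionally writes the interchange files and the manifest (JSON)
#' to a directory.
#'
#' @param condition one of [conditions()].
#' @param seed integer seed controlling every stochastic stage.
#' @param n_genes,chrom_length_bp genome size (defaults: 40 genes,
#'   300 kb).
#' @param config optional `sim_config`; built from `condition` and `seed`
#'   when `NULL`.
#' @param genome_seed seed of the genome draw; defaults to 1 so that
#'   different `seed`s replicate the experiment on the same genome, as
#'   replicate libraries from one strain would.
#' @param outdir if not `NULL`, write outputs (BED annotation, bedGraph
#'   tracks, matrix TSVs, loop table, `manifest.json`) there.
#' @return list with `annotation`, `barriers`, `config`, `snapshots`,
#'   `map_raw`, `map_norm`, `tracks`, `insulation`, `loops`,
#'   `cohesin_sites`, `manifest`.
#' @export
run_pipeline <- function(condition = "WT_G2M", seed = 1L,
                         n_genes = 40L, chrom_length_bp = 300000L,
                         config = NULL, genome_seed = 1L, outdir = NULL) {
  check_condition(condition)
  ann <- make_genome(n_genes, chrom_length_bp, seed = genome_seed)
  barriers <- derive_barriers(ann, condition)
  if (is.null(config)) {
    config <- simulation_config(condition = condition, seed = seed)
  }
  snapshots <- simulate_population(ann, barriers, config)
  map_raw <- render_contact_map(snapshots, ann, config)
  tracks <- render_tracks(snapshots, ann, condition)
  map_norm <- vc_sqrt_normalize(map_raw)
  ins <- insulation_score(map_norm, window_bp = 40000)
  loops <- call_loops(map_norm)
  coh_peaks <- call_peaks(tracks$cohesin, threshold = 2.0,
                          exclusions = ann$ltrs)
  loops <- filter_by_anchors(loops, coh_peaks,
                             slack_bp = ann$bin_size_bp)
  manifest <- list(
    tool = "loopex",
    version = as.character(utils::packageVersion("loopex")),
    condition = condition,
    seed = seed,
    n_genes = n_genes,
    chrom_length_bp = chrom_length_bp,
    n_snapshots = length(snapshots),
    mean_extruders = mean(extruder_counts(snapshots)),
    read_depth = config$read_depth,
    n_cohesin_peaks = nrow(coh_peaks),
    n_loops = nrow(loops),
    n_loops_anchored = sum(loops$anchor_filter_passed)
  )
  out <- list(annotation = ann, barriers = barriers, config = config,
              snapshots = snapshots, map_raw = map_raw, map_norm = map_norm,
              tracks = tracks, insulation = ins, loops = loops,
              cohesin_sites = coh_peaks, manifest = manifest)
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    write_genome_bed(ann, file.path(outdir, "annotation"))
    write_matrix_tsv(map_raw, file.path(outdir, "map_raw.tsv"))
    write_matrix_tsv(map_norm, file.path(outdir, "map_vcsqrt.tsv"))
    for (nm in names(tracks)) {
      write_bedgraph(tracks[[nm]], file.path(outdir, paste0(nm, ".bedGraph")))
    }
    utils::write.table(loops, file.path(outdir, "loops.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}
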