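#' Pipeline run configuration
#'
#' Collects every stage parameter of the workflow with the standard defaults
#' (QC call rate 0.90 / MAF 0.05 / individual missingness 0.10; the
#' 20/0/2-window, 20-SNP, 2000-kb, 100-kb-per-SNP, 500-kb-gap ROH criteria;
#' island percentile 0.001; 500-kb windows in 250-kb steps with the 0.0005
#' window percentile and a 5-SNP minimum; autosome length 2522 Mb).
#'
#' @param input path stem of a PLINK fileset, or \code{NULL} to simulate.
#' @param dialect PLINK dialect of \code{input}.
#' @param sim a \code{\link{sim_config}} used when \code{input} is
#'   \code{NULL}.
#' @param group_map named character vector population -> wet/dry/none;
#'   \code{NULL} keeps the groups already present (simulated data carry
#'   them).
#' @param out_dir output directory.
#' @param seed integer seed (simulation is the only stochastic stage).
#' @param qc,roh,islands,fst named lists overriding stage parameters.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(input = NULL, dialect = "binary", sim = sim_config(),
                       group_map = NULL, out_dir = "rohfst_out", seed = 1L,
                       qc = list(), roh = list(), islands = list(),
                       fst = list()) {
  defaults <- list(
    qc = list(snp_call_rate = 0.90, maf_min = 0.05, ind_max_missing = 0.10),
    roh = as.list(unclass(roh_params())),
    islands = list(top_fraction = 0.001),
    fst = list(window_kb = 500, step_kb = 250, min_snps = 5,
               top_fraction = 0.0005),
    l_aut_mb = 2522
  )
  defaults$qc[names(qc)] <- qc
  defaults$roh[names(roh)] <- roh
  defaults$islands[names(islands)] <- islands
  defaults$fst[names(fst)] <- fst
  structure(list(input = input, dialect = dialect, sim = sim,
                 group_map = group_map, out_dir = out_dir,
                 seed = as.integer(seed), params = defaults),
            class = "run_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis workflow
#'
#' QC -> per-breed diversity -> ROH segments and FROH -> per-breed ROH
#' islands -> windowed FST for every wet/dry contrast -> Reynolds and IBS
#' distances with classical MDS. Writes one TSV per report table, distance
#' matrices in PHYLIP and NEXUS formats, MDS coordinates, and a JSON
#' manifest (parameters, stage counts, seed). FST stages are skipped, with
#' the reason logged, when fewer than two metapopulation groups are present;
#' distance stages require at least two populations.
#'
#' @param config a \code{\link{run_config}}.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list(seed = config$seed, params = config$params,
                   stages = list())

  stage <- "input"
  res <- tryCatch({
    ds <- if (is.null(config$input)) {
      cfg <- config$sim
      cfg$seed <- config$seed
      simulate_dataset(cfg)$dataset
    } else read_plink(config$input, config$dialect)
    if (!is.null(config$group_map)) ds <- assign_groups(ds, config$group_map)
    manifest$stages$input <- list(n_samples = nrow(ds$samples),
                                  n_snps = nrow(ds$variants))

    stage <- "qc"
    qc <- do.call(qc_filter, c(list(ds), config$params$qc))
    ds <- qc$dataset
    write_qc_report(qc$report, out("qc_report.tsv"))
    manifest$stages$qc <- unclass(qc$report)[1:7]

    stage <- "diversity"
    div <- diversity_table(ds)

    stage <- "roh"
    rp <- do.call(roh_params, config$params$roh)
    segments <- detect_roh(ds, params = rp)
    .write_tsv(segments, out("roh_segments.tsv"))
    froh_ind <- froh(segments, ds, config$params$l_aut_mb, by = "sample")
    froh_pop <- froh(segments, ds, config$params$l_aut_mb,
                     by = "population")
    .write_tsv(froh_ind, out("froh_individual.tsv"))
    .write_tsv(froh_pop, out("froh_population.tsv"))
    div$froh <- froh_pop$f_roh[match(div$population, froh_pop$population)]
    .write_tsv(div, out("diversity.tsv"))
    manifest$stages$roh <- list(n_segments = nrow(segments))

    stage <- "roh_islands"
    pops <- unique(ds$samples$population)
    freqs <- do.call(rbind, lapply(pops, function(p)
      snp_roh_frequency(segments, ds, p)))
    .write_tsv(freqs, out("snp_roh_frequency.tsv"))
    islands <- do.call(rbind, lapply(pops, function(p)
      roh_islands(freqs[freqs$population == p, , drop = FALSE],
                  config$params$islands$top_fraction)))
    .write_tsv(islands, out("roh_islands.tsv"))
    manifest$stages$roh_islands <- list(n_islands = nrow(islands))

    stage <- "fst_scan"
    groups_present <- unique(ds$samples$group)
    if (all(c("wet", "dry") %in% groups_present)) {
      contrasts <- build_contrasts(ds)
      win_all <- list(); sig_all <- list()
      for (ct in contrasts) {
        comp <- wc_components(ds, ct$pop_a, ct$pop_b)
        win <- windowed_fst(comp, config$params$fst$window_kb,
                            config$params$fst$step_kb, contrast = ct$label)
        sig <- significant_windows(win, config$params$fst$min_snps,
                                   config$params$fst$top_fraction)
        win_all[[ct$label]] <- win
        sig_all[[ct$label]] <- sig
      }
      .write_tsv(do.call(rbind, win_all), out("fst_windows.tsv"))
      sig_tab <- do.call(rbind, sig_all)
      rownames(sig_tab) <- NULL
      .write_tsv(sig_tab, out("fst_significant_windows.tsv"))
      manifest$stages$fst_scan <- list(
        n_contrasts = length(contrasts),
        n_significant = nrow(sig_tab))
    } else {
      message("FST stages skipped: need both wet and dry groups, found: ",
              paste(groups_present, collapse = ", "))
      manifest$stages$fst_scan <- list(skipped = "need wet and dry groups")
    }

    stage <- "popstruct"
    if (length(pops) >= 2L) {
      rd <- reynolds_distance(ds)
      write_phylip(rd, out("reynolds.phylip"))
      write_nexus_distances(rd, out("reynolds.nex"))
      ibs <- ibs_distance(ds)
      mds <- classical_mds(ibs, k = min(2L, nrow(ibs) - 1L))
      coords <- data.frame(sample_id = mds$labels, mds$points)
      names(coords)[-1] <- paste0("dim", seq_len(ncol(mds$points)))
      .write_tsv(coords, out("mds_coordinates.tsv"))
      manifest$stages$popstruct <- list(
        n_populations = length(pops),
        mds_var_explained = mds$var_explained)
    } else {
      message("distance stages skipped: fewer than two populations")
      manifest$stages$popstruct <- list(skipped = "single population")
    }
    manifest
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  jsonlite::write_json(res, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(res)
}

#' Manhattan-style plot of windowed FST
#'
#' @param windows a \code{\link{windowed_fst}} table (one contrast).
#' @param threshold optional horizontal reference line.
#' @param ... passed to \code{plot}.
#' @export
plot_fst_windows <- function(windows, threshold = NULL, ...) {
  chroms <- unique(windows$chrom)
  offset <- c(0, cumsum(vapply(chroms, function(ch)
    max(windows$end_bp[windows$chrom == ch]), numeric(1))))
  x <- windows$start_bp + offset[match(windows$chrom, chroms)]
  graphics::plot(x, windows$weighted_fst,
                 col = match(windows$chrom, chroms) %% 2 + 1, pch = 16,
                 cex = 0.5, xlab = "genome position",
                 ylab = "weighted FST", ...)
  if (!is.null(threshold)) graphics::abline(h = threshold, col = "red")
  invisible(windows)
}
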