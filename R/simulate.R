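#' Simulation configuration
#'
#' Describes a multi-breed SNP-array dataset generated under the
#' Balding-Nichols drift model: ancestral allele frequencies are drawn
#' uniformly on (0.05, 0.95), each breed's frequency from
#' \eqn{Beta(p(1-F)/F, (1-p)(1-F)/F)} with its drift coefficient F, and
#' genotypes as Hardy-Weinberg draws. Selective sweeps shift a target
#' metapopulation's frequencies away from the ancestral majority allele
#' (preserving the full wet/dry differential near either frequency edge);
#' homozygous tracts overwrite carrier genotypes with a single shared
#' homozygous haplotype. Missingness is applied last, uniformly at random.
#'
#' The defaults mirror the demo study design: four island breeds (two
#' adapted to wet, two to dry conditions) with sample sizes 60/61/64/39,
#' two ~120 Mb autosomes carrying 5000 SNPs, per-breed drift coefficients
#' of 0.05-0.10, and 1% missing genotypes.
#'
#' @param seed integer seed; the same config is bit-reproducible.
#' @param breeds character vector of breed codes.
#' @param samples_per_breed integer vector, same length as \code{breeds}.
#' @param groups metapopulation label per breed (\code{"wet"}, \code{"dry"},
#'   \code{"none"}).
#' @param drift_f per-breed drift coefficient in (0, 1).
#' @param chrom_lengths_bp named numeric vector of chromosome spans.
#' @param n_snps total SNP count across chromosomes.
#' @param missing_rate fraction of genotypes set missing.
#' @param sweeps list of sweep specs:
#'   \code{list(chrom, start_bp, end_bp, target_group, delta)}.
#' @param roh_tracts list of tract specs:
#'   \code{list(population, chrom, start_bp, end_bp, carrier_fraction)}.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       breeds = c("MAJ", "PAL", "TIN", "TIS"),
                       samples_per_breed = c(60L, 61L, 64L, 39L),
                       groups = c("dry", "wet", "wet", "dry"),
                       drift_f = c(0.05, 0.10, 0.06, 0.05),
                       chrom_lengths_bp = c("1" = 120e6, "2" = 120e6),
                       n_snps = 5000L,
                       missing_rate = 0.01,
                       sweeps = list(),
                       roh_tracts = list()) {
  stopifnot(length(breeds) == length(samples_per_breed),
            length(breeds) == length(groups),
            length(breeds) == length(drift_f),
            all(drift_f > 0), all(drift_f < 1),
            missing_rate >= 0, missing_rate < 1,
            n_snps > 0, all(chrom_lengths_bp > 0))
  structure(list(
    seed = as.integer(seed), breeds = breeds,
    samples_per_breed = as.integer(samples_per_breed),
    groups = groups, drift_f = drift_f,
    chrom_lengths_bp = chrom_lengths_bp, n_snps = as.integer(n_snps),
    missing_rate = missing_rate, sweeps = sweeps, roh_tracts = roh_tracts
  ), class = "sim_config")
}

# SNP positions: distinct cells of a 5-kb grid, guaranteeing >= 5 kb spacing
.sim_positions <- function(chrom_lengths_bp, n_snps) {
  chroms <- names(chrom_lengths_bp)
  n_per <- diff(round(seq(0, n_snps, length.out = length(chroms) + 1)))
  out <- list()
  for (k in seq_along(chroms)) {
    cells <- floor(chrom_lengths_bp[k] / 5000) - 1L
    if (n_per[k] > cells) stop("chromosome ", chroms[k],
                               " too short for ", n_per[k], " SNPs")
    pos <- sort(sample.int(cells, n_per[k])) * 5000L
    out[[k]] <- data.frame(chrom = chroms[k], pos_bp = pos,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate a multi-breed SNP-array dataset with known truth
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with the \code{dataset} (an \code{\link{snp_dataset}}) and
#'   \code{truth}: the config plus realized ancestral and per-breed allele
#'   frequencies and per-sample tract carrier assignments.
#' @export
simulate_dataset <- function(config) {
  set.seed(config$seed)
  map <- .sim_positions(config$chrom_lengths_bp, config$n_snps)
  m <- nrow(map)
  map$snp_id <- paste0("snp_", map$chrom, "_", map$pos_bp)
  p_anc <- stats::runif(m, 0.05, 0.95)
  nb <- length(config$breeds)
  # per-breed drifted frequencies (Balding-Nichols)
  p_breed <- matrix(NA_real_, nrow = m, ncol = nb,
                    dimnames = list(NULL, config$breeds))
  for (k in seq_len(nb)) {
    f <- config$drift_f[k]
    p_breed[, k] <- stats::rbeta(m, p_anc * (1 - f) / f,
                                 (1 - p_anc) * (1 - f) / f)
  }
  # sweeps: shift the target group's frequencies away from the ancestral
  # majority allele (toward the farther boundary), clipped away from
  # fixation; this preserves the full wet/dry differential for ancestral
  # frequencies near either edge
  for (sw in config$sweeps) {
    in_sw <- map$chrom == sw$chrom & map$pos_bp >= sw$start_bp &
      map$pos_bp <= sw$end_bp
    if (!any(in_sw)) stop("sweep on chromosome ", sw$chrom,
                          " contains no SNP")
    dir <- ifelse(p_anc[in_sw] >= 0.5, -1, 1)
    tgt <- which(config$groups == sw$target_group)
    for (k in tgt)
      p_breed[in_sw, k] <- pmin(pmax(p_breed[in_sw, k] + dir * sw$delta,
                                     0.01), 0.99)
  }
  n <- sum(config$samples_per_breed)
  breed_of <- rep(config$breeds, config$samples_per_breed)
  group_of <- rep(config$groups, config$samples_per_breed)
  samples <- data.frame(
    sample_id = paste0(breed_of, "_", stats::ave(seq_len(n), breed_of,
                                                 FUN = seq_along)),
    population = breed_of, group = group_of, stringsAsFactors = FALSE)
  geno <- matrix(NA_integer_, nrow = n, ncol = m)
  for (k in seq_len(nb)) {
    rows <- which(breed_of == config$breeds[k])
    geno[rows, ] <- matrix(
      stats::rbinom(length(rows) * m, 2, rep(p_breed[, k], each = length(rows))),
      nrow = length(rows))
  }
  # homozygous tracts: one shared haplotype copied over both chromosomes of
  # each carrier
  carriers <- list()
  for (ti in seq_along(config$roh_tracts)) {
    tr <- config$roh_tracts[[ti]]
    in_tr <- which(map$chrom == tr$chrom & map$pos_bp >= tr$start_bp &
                     map$pos_bp <= tr$end_bp)
    if (length(in_tr) < 20L)
      stop("tract ", ti, " (", tr$population, " ", tr$chrom, ":",
           tr$start_bp, "-", tr$end_bp, ") spans only ", length(in_tr),
           " SNPs at the realized spacing; >= 20 required")
    k <- match(tr$population, config$breeds)
    hap <- stats::rbinom(length(in_tr), 1, p_breed[in_tr, k])
    rows <- which(breed_of == tr$population)
    n_car <- max(1L, round(tr$carrier_fraction * length(rows)))
    car <- sort(sample(rows, n_car))
    geno[car, in_tr] <- matrix(rep(2L * hap, each = n_car), nrow = n_car)
    carriers[[ti]] <- samples$sample_id[car]
  }
  if (config$missing_rate > 0) {
    miss <- stats::runif(length(geno)) < config$missing_rate
    geno[miss] <- NA_integer_
  }
  variants <- data.frame(snp_id = map$snp_id, chrom = map$chrom,
                         pos_bp = map$pos_bp, a1 = "A", a2 = "B",
                         stringsAsFactors = FALSE)
  ds <- snp_dataset(geno, samples, variants)
  truth <- list(config = config, ancestral_freq = p_anc,
                breed_freq = p_breed, tract_carriers = carriers)
  list(dataset = ds, truth = truth)
}

#' Write a simulated fixture to disk
#'
#' Simulates from a config, writes the dataset as a PLINK fileset and the
#' truth (config, sweep and tract coordinates, carriers) as JSON alongside,
#' so the fixture can be regenerated from the JSON alone.
#'
#' @param config a \code{\link{sim_config}}.
#' @param prefix output path stem.
#' @param dialect PLINK dialect, \code{"binary"} or \code{"text"}.
#' @return list with the dataset and truth, invisibly.
#' @export
write_fixture <- function(config, prefix, dialect = c("binary", "text")) {
  dialect <- match.arg(dialect)
  sim <- simulate_dataset(config)
  write_plink(sim$dataset, prefix, dialect)
  cfg_json <- unclass(config)
  cfg_json$chrom_lengths_bp <- as.list(cfg_json$chrom_lengths_bp)
  truth <- list(
    config = cfg_json,
    tract_carriers = sim$truth$tract_carriers
  )
  jsonlite::write_json(truth, paste0(prefix, ".truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sim)
}

#' Rebuild a simulation config from a fixture's truth JSON
#'
#' @param path path to a \code{.truth.json} written by
#'   \code{\link{write_fixture}}.
#' @return the embedded \code{\link{sim_config}}.
#' @export
read_fixture_config <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- tr$config
  cl <- unlist(cfg$chrom_lengths_bp)
  sweeps <- list()
  if (!is.null(cfg$sweeps) && length(cfg$sweeps))
    sweeps <- if (is.data.frame(cfg$sweeps))
      lapply(seq_len(nrow(cfg$sweeps)), function(i) as.list(cfg$sweeps[i, ]))
    else cfg$sweeps
  tracts <- list()
  if (!is.null(cfg$roh_tracts) && length(cfg$roh_tracts))
    tracts <- if (is.data.frame(cfg$roh_tracts))
      lapply(seq_len(nrow(cfg$roh_tracts)),
             function(i) as.list(cfg$roh_tracts[i, ]))
    else cfg$roh_tracts
  sim_config(seed = cfg$seed, breeds = cfg$breeds,
             samples_per_breed = cfg$samples_per_breed,
             groups = cfg$groups, drift_f = cfg$drift_f,
             chrom_lengths_bp = cl, n_snps = cfg$n_snps,
             missing_rate = cfg$missing_rate,
             sweeps = sweeps, roh_tracts = tracts)
}
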