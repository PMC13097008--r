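# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# Small landscape for unit tests: 12x12 grid, 60 trees at 6 sites,
# 10 adaptive among 130 loci.
small_fixture <- function() {
  if (!is.null(.fixture_cache$small)) return(.fixture_cache$small)
  lc <- landscape_config(n_cells_x = 12, n_cells_y = 12, cell_size_km = 5,
                         n_individuals = 60, n_sites = 6,
                         n_neutral_loci = 120, n_adaptive_loci = 10,
                         seed = 42)
  grids <- make_climate_grids(lc)
  sim <- suppressMessages(simulate_genotypes(lc, grids))
  gmi <- impute_major(sim$gm)
  ext <- extract_at_points(grids$recent, sim$coords)
  X <- as.matrix(ext[, grids$recent$variables])
  .fixture_cache$small <- list(lc = lc, grids = grids, sim = sim, gmi = gmi,
                               ext = ext, X = X)
  .fixture_cache$small
}

# Engines fitted on the small fixture's true adaptive loci.
small_engines <- function() {
  if (!is.null(.fixture_cache$engines)) return(.fixture_cache$engines)
  fx <- small_fixture()
  Y <- fx$gmi$dosages[, fx$sim$truth$adaptive_locus_ids]
  gf <- suppressWarnings(fit_gradient_forest(Y, fx$X, n_trees = 100, seed = 9))
  rda <- fit_rda_offset(Y, fx$X)
  fr <- site_allele_freqs(fx$gmi, fx$sim$truth$adaptive_locus_ids)
  sc <- t(sapply(rownames(fr), function(s)
    colMeans(fx$X[fx$gmi$samples$site == s, , drop = FALSE])))
  gdm <- fit_gdm(fr, sc)
  .fixture_cache$engines <- list(gf = gf, rda = rda, gdm = gdm)
  .fixture_cache$engines
}

# Hand-written VCF with known depth / allele structure.
# 10 samples; records:
#  r1: biallelic, all called, one genotype at DP 4 (-> masked), one at DP 5
#  r2: triallelic (dropped)
#  r3: monomorphic ref (MAF 0)
#  r4: exactly 1 of 10 genotypes missing (./.) -> 10% missingness
#  r5: common SNP, MAF 0.5
write_toy_vcf <- function(path) {
  samples <- paste0("s", 1:10)
  gt <- function(g, dp) paste0(g, ":", dp)
  rec <- function(chrom, pos, id, ref, alt, cells)
    paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT:DP", cells),
          collapse = "\t")
  r1 <- rec("chr1", 100, "r1", "A", "G",
            c(gt("0/1", 4), gt("0/1", 5), gt("0/0", 20), gt("1/1", 20),
              rep(gt("0/0", 20), 6)))
  r2 <- rec("chr1", 200, "r2", "A", "G,T",
            rep(gt("0/1", 20), 10))
  r3 <- rec("chr1", 300, "r3", "C", "T", rep(gt("0/0", 20), 10))
  r4 <- rec("chr1", 400, "r4", "G", "A",
            c(gt("./.", 0), gt("0/1", 20), gt("1/1", 20), rep(gt("0/0", 20), 7)))
  r5 <- rec("chr1", 500, "r5", "T", "C",
            c(rep(gt("0/0", 20), 5), rep(gt("1/1", 20), 5)))
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    r1, r2, r3, r4, r5), path)
  path
}

# Construct a genotype matrix directly from a dosage matrix.
gm_from_dosages <- function(dos, chrom = "chr1") {
  n_snp <- ncol(dos)
  genotype_matrix(dos,
                  variants = data.frame(id = paste0("v", seq_len(n_snp)),
                                        chrom = chrom, pos = seq_len(n_snp) * 100,
                                        ref = "A", alt = "G",
                                        mean_depth = 20),
                  samples = data.frame(id = paste0("s", seq_len(nrow(dos))),
                                       lon = 0, lat = 0, site = "x"))
}

# A tiny two-variable climate grid with tmx a linear west-east gradient.
gradient_grid <- function(n = 6, scenario = scenario_key(), tmx_add = 0) {
  cells <- data.frame(cell_id = sprintf("g%02d", 1:n),
                      x = (1:n) - 0.5, y = 0.5,
                      lon = ((1:n) - 0.5) / 100, lat = 0.5 / 100)
  vals <- cbind(tmx = seq(-1.5, 1.5, length.out = n) + tmx_add,
                cwd = rep(0.25, n))
  climate_grid(cells, vals, scenario, cell_size = 1)
}
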