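#' Configuration for the synthetic BMPC repertoire generator
#'
#' Builds and validates the parameter set for [simulate_repertoire()]. The
#' defaults encode the generative model the pipeline is designed to probe:
#' memory-B-cell (MBC) recall produces singlets or isogenic clones with
#' lower somatic hypermutation (SHM), lower surface CD19 and higher JCHAIN,
#' while direct germinal-center (GC) export produces heterogenic clones
#' with higher SHM and higher CD19.
#'
#' @param n_cells Number of cells to emit.
#' @param n_donors Number of donors; donors are split round-robin over
#'   three sequencing batches.
#' @param frac_allergic_donors Fraction of donors flagged as food-allergic
#'   (default 2/3, i.e. six of nine donors).
#' @param origin_mix Probability that a clone is of GC-export origin (the
#'   remainder are MBC-recall); with sizes independent of origin this is
#'   also the expected fraction of GC cells.
#' @param clone_size_distribution List with `name` (only `"zeta"`),
#'   `exponent` and `max_size`: clone sizes are drawn from a truncated
#'   power law P(s) proportional to s^-exponent, s = 1..max_size. The
#'   default (exponent 2.5, max 50) makes roughly 40-50% of cells singlets.
#' @param shm_mbc_mean,shm_gc_mean Mean planted SHM (percent of heavy-chain
#'   nucleotides mutated) for MBC- and GC-origin clones.
#' @param shm_sd Between-clone SD of planted SHM (percent).
#' @param intraclonal_mut_rate_gc Poisson mean of private (per-cell extra)
#'   mutations within GC-origin clones. MBC-origin clones copy one sequence
#'   identically.
#' @param cd19_effect Planted shift, in Z-score units of the log CD19
#'   antibody-capture signal, between GC and MBC cells.
#' @param isotype_probs 2 x 9 numeric matrix (rows `MBC`, `GC`; columns the
#'   nine IGHC subclass genes) of isotype probabilities per origin; each
#'   row sums to 1.
#' @param ighc_count_mean Poisson mean of IGHC transcript counts for a
#'   cell's true isotype gene.
#' @param ambient_rate Poisson mean of contaminating counts for each of the
#'   other eight IGHC genes.
#' @param vdj_dropout Probability that a cell lacks a VDJ record.
#' @param qc_fail_rates Named fractions `mito`, `rna`, `lineage` of cells
#'   planted to violate each quality-control rule (disjoint sets).
#' @param jchain_effect Planted log-scale shift of JCHAIN expression in
#'   MBC-origin cells relative to GC-origin cells.
#' @param isotype_donor_alpha Optional Dirichlet concentration for
#'   donor-level variation of isotype composition; `Inf` (default)
#'   disables it.
#' @param seed Integer seed; identical config (including seed) yields
#'   byte-identical output tables.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 2000,
                       n_donors = 9,
                       frac_allergic_donors = 2 / 3,
                       origin_mix = 0.5,
                       clone_size_distribution = list(name = "zeta",
                                                      exponent = 2.5,
                                                      max_size = 50),
                       shm_mbc_mean = 4,
                       shm_gc_mean = 8,
                       shm_sd = 2,
                       intraclonal_mut_rate_gc = 2,
                       cd19_effect = 1.5,
                       isotype_probs = default_isotype_probs(),
                       ighc_count_mean = 50,
                       ambient_rate = 0.5,
                       vdj_dropout = 0.1,
                       qc_fail_rates = c(mito = 0.02, rna = 0.02,
                                         lineage = 0.02),
                       jchain_effect = 1,
                       isotype_donor_alpha = Inf,
                       seed = 1L) {
  cfg <- list(
    n_cells = as.integer(n_cells), n_donors = as.integer(n_donors),
    frac_allergic_donors = frac_allergic_donors, origin_mix = origin_mix,
    clone_size_distribution = clone_size_distribution,
    shm_mbc_mean = shm_mbc_mean, shm_gc_mean = shm_gc_mean,
    shm_sd = shm_sd, intraclonal_mut_rate_gc = intraclonal_mut_rate_gc,
    cd19_effect = cd19_effect, isotype_probs = isotype_probs,
    ighc_count_mean = ighc_count_mean, ambient_rate = ambient_rate,
    vdj_dropout = vdj_dropout, qc_fail_rates = qc_fail_rates,
    jchain_effect = jchain_effect,
    isotype_donor_alpha = isotype_donor_alpha,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Default per-origin isotype probabilities
#'
#' MBC-origin cells are biased toward IgG and IgM (the classes enriched in
#' the CD19-low compartment), GC-origin cells toward IgA (enriched in the
#' CD19-high compartment).
#'
#' @return A 2 x 9 matrix with rows `MBC`, `GC` and columns the IGHC
#'   subclass genes.
#' @export
default_isotype_probs <- function() {
  m <- rbind(
    MBC = c(IGHM = 0.15, IGHD = 0.02, IGHG1 = 0.30, IGHG2 = 0.15,
            IGHG3 = 0.05, IGHG4 = 0.02, IGHA1 = 0.20, IGHA2 = 0.08,
            IGHE = 0.03),
    GC  = c(IGHM = 0.05, IGHD = 0.01, IGHG1 = 0.20, IGHG2 = 0.10,
            IGHG3 = 0.04, IGHG4 = 0.02, IGHA1 = 0.40, IGHA2 = 0.15,
            IGHE = 0.03)
  )
  m[, ighc_genes()]
}

validate_sim_config <- function(cfg) {
  frac_fields <- c("frac_allergic_donors", "origin_mix", "vdj_dropout")
  for (f in frac_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1)
      stop("sim_config: `", f, "` must be a single fraction in [0, 1]")
  }
  if (any(cfg$qc_fail_rates < 0) || any(cfg$qc_fail_rates > 1) ||
      sum(cfg$qc_fail_rates) > 1)
    stop("sim_config: `qc_fail_rates` must be fractions summing to at most 1")
  if (!setequal(names(cfg$qc_fail_rates), c("mito", "rna", "lineage")))
    stop("sim_config: `qc_fail_rates` must be named mito, rna, lineage")
  p <- cfg$isotype_probs
  if (!is.matrix(p) || nrow(p) != 2 ||
      !setequal(rownames(p), c("MBC", "GC")) ||
      !setequal(colnames(p), ighc_genes()))
    stop("sim_config: `isotype_probs` must be a 2 x 9 matrix with rows ",
         "MBC/GC and the IGHC subclass genes as columns")
  if (any(p < 0) || any(abs(rowSums(p) - 1) > 1e-9))
    stop("sim_config: each `isotype_probs` row must sum to 1 (within 1e-9)")
  d <- cfg$clone_size_distribution
  if (!identical(d$name, "zeta") || d$exponent <= 1 || d$max_size < 1)
    stop("sim_config: clone_size_distribution must be ",
         "list(name = 'zeta', exponent > 1, max_size >= 1)")
  for (f in c("shm_mbc_mean", "shm_gc_mean", "shm_sd",
              "intraclonal_mut_rate_gc", "ighc_count_mean", "ambient_rate",
              "jchain_effect"))
    if (cfg[[f]] < 0) stop("sim_config: `", f, "` must be non-negative")
  if (cfg$n_cells < 1 || cfg$n_donors < 1)
    stop("sim_config: n_cells and n_donors must be positive")
  invisible(cfg)
}

#' Mutate a nucleotide sequence at exactly n distinct positions
#'
#' Substitutes `n_mut` distinct positions of `germline` with a different
#' base, drawing positions and replacement bases from the current RNG
#' stream. Positions listed in `protect` are never touched (the simulator
#' uses this to keep the CDR3 segment invariant within a clone).
#'
#' @param germline Nucleotide string over A/C/G/T.
#' @param n_mut Number of positions to mutate.
#' @param protect Integer vector of 1-based positions to exclude.
#' @return A string of equal length with hamming distance exactly `n_mut`
#'   to `germline`.
#' @examples
#' set.seed(1)
#' mutate_sequence("ATGCATGC", 3)
#' @export
mutate_sequence <- function(germline, n_mut, protect = integer(0)) {
  chars <- strsplit(germline, "")[[1]]
  if (!all(chars %in% c("A", "C", "G", "T")))
    stop("mutate_sequence: germline must be over the A/C/G/T alphabet")
  eligible <- setdiff(seq_along(chars), protect)
  if (n_mut > length(eligible))
    stop("mutate_sequence: n_mut (", n_mut, ") exceeds the number of ",
         "mutable positions (", length(eligible), ")")
  if (n_mut == 0) return(germline)
  pos <- if (length(eligible) == 1) eligible else
    sample(eligible, n_mut, replace = FALSE)
  for (i in pos) {
    alt <- setdiff(c("A", "C", "G", "T"), chars[i])
    chars[i] <- alt[sample.int(3, 1)]
  }
  paste(chars, collapse = "")
}

# truncated power-law clone sizes, drawn until n_cells is exactly covered
draw_clone_sizes <- function(n_cells, dist) {
  s <- seq_len(dist$max_size)
  pr <- s^(-dist$exponent)
  sizes <- integer(0)
  total <- 0L
  while (total < n_cells) {
    k <- sample(s, 1, prob = pr)
    k <- min(k, n_cells - total)
    sizes <- c(sizes, k)
    total <- total + k
  }
  sizes
}

# rejection-sample a CDR3 amino-acid string keeping hamming distance >= 3
# to every previously accepted CDR3 of the same (v, j, length) partition
sample_cdr3 <- function(len, existing) {
  aa <- names(.codon_of)
  repeat {
    core <- paste(sample(aa, len - 2, replace = TRUE), collapse = "")
    cand <- paste0("C", core, "W")
    ok <- TRUE
    for (e in existing) {
      if (nchar(e) == nchar(cand)) {
        d <- sum(strsplit(e, "")[[1]] != strsplit(cand, "")[[1]])
        if (d < 3) { ok <- FALSE; break }
      }
    }
    if (ok) return(cand)
  }
}

#' Plan the clonal families of a synthetic repertoire
#'
#' Draws, from the current RNG stream, a list of clone plans whose sizes
#' sum exactly to `n_cells`: each plan carries the clone's origin (MBC or
#' GC), donor, isotype, V/J template, CDR3 (inter-clone hamming distance
#' at least 3 within a V/J/length partition), planted trunk-mutation count
#' and the per-member private-mutation loads. MBC-origin multi-cell clones
#' share one sequence (all private loads 0); GC-origin multi-cell clones
#' are guaranteed at least two distinct mutation loads, so at least two
#' unique sequences.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with one row per clone; `private_mut` is a list column
#'   of per-member extra mutation counts.
#' @export
sample_family_plan <- function(config) {
  validate_sim_config(config)
  tmpl <- germline_templates()
  vs <- tmpl[tmpl$segment == "V", ]
  js <- tmpl[tmpl$segment == "J", ]

  sizes <- draw_clone_sizes(config$n_cells, config$clone_size_distribution)
  n_clones <- length(sizes)
  origin <- ifelse(stats::runif(n_clones) < config$origin_mix, "GC", "MBC")
  donors <- sprintf("D%02d", seq_len(config$n_donors))
  donor <- sample(donors, n_clones, replace = TRUE)

  # per-donor isotype probabilities (optionally Dirichlet-dispersed)
  probs <- config$isotype_probs
  donor_probs <- lapply(donors, function(d) {
    if (is.finite(config$isotype_donor_alpha)) {
      t(apply(probs, 1, function(p) {
        g <- stats::rgamma(length(p), shape = config$isotype_donor_alpha * p)
        g / sum(g)
      }))
    } else probs
  })
  names(donor_probs) <- donors

  shm_mean <- ifelse(origin == "GC", config$shm_gc_mean, config$shm_mbc_mean)
  target_shm <- pmax(0, stats::rnorm(n_clones, shm_mean, config$shm_sd))

  cdr3_pool <- list()  # key: v|j|len -> accepted CDR3s
  vi <- sample.int(nrow(vs), n_clones, replace = TRUE)
  ji <- sample.int(nrow(js), n_clones, replace = TRUE)
  lens <- sample(12:18, n_clones, replace = TRUE)
  cdr3s <- character(n_clones)
  iso_gene <- character(n_clones)
  trunk <- integer(n_clones)
  private_mut <- vector("list", n_clones)
  for (i in seq_len(n_clones)) {
    key <- paste(vs$name[vi[i]], js$name[ji[i]], lens[i], sep = "|")
    cdr3s[i] <- sample_cdr3(lens[i], cdr3_pool[[key]])
    cdr3_pool[[key]] <- c(cdr3_pool[[key]], cdr3s[i])

    pr <- donor_probs[[donor[i]]][origin[i], ]
    iso_gene[i] <- sample(ighc_genes(), 1, prob = pr)

    full_len <- nchar(vs$sequence[vi[i]]) + 3 * lens[i] +
      nchar(js$sequence[ji[i]])
    mutable_len <- full_len - 3 * lens[i]
    trunk[i] <- min(round(target_shm[i] / 100 * full_len), mutable_len)

    size <- sizes[i]
    if (origin[i] == "GC" && size >= 2) {
      repeat {
        priv <- stats::rpois(size, config$intraclonal_mut_rate_gc)
        if (length(unique(priv)) >= 2) break
      }
      # private loads must fit the remaining mutable positions
      priv <- pmin(priv, mutable_len - trunk[i])
      if (length(unique(priv)) < 2) priv[1] <- max(0, priv[1] - 1)
    } else {
      priv <- rep(0L, size)
    }
    private_mut[[i]] <- as.integer(priv)
  }
  tibble::tibble(
    clone_id = sprintf("SIM%04d", seq_len(n_clones)), size = sizes,
    origin = origin, donor = donor, isotype_gene = iso_gene,
    v_name = vs$name[vi], j_name = js$name[ji], cdr3_aa = cdr3s,
    v_seq = vs$sequence[vi], j_seq = js$sequence[ji],
    target_shm = target_shm, trunk_mut = trunk,
    private_mut = private_mut
  )
}

ighc_genes <- function() {
  c("IGHM", "IGHD", "IGHG3", "IGHG1", "IGHA1", "IGHG2", "IGHG4", "IGHE",
    "IGHA2")
}

lineage_genes <- function() {
  c("CD3E", "NKG7", "PRF1", "S100A9", "FCGR3A", "CD14", "COL1A1", "APOE",
    "CSF3R", "HBB")
}

#' Simulate a paired GEX + VDJ + metadata BMPC dataset with ground truth
#'
#' Generates, deterministically from `config$seed`, the three input tables
#' the analysis pipeline consumes plus per-cell and per-clone ground
#' truth:
#'
#' * `vdj` — AIRR-dialect rearrangement rows (`cell_id`, `v_call`,
#'   `j_call`, `junction_aa`, `sequence`, `germline_alignment`, `c_call`),
#'   one per cell that escaped VDJ dropout. Planted mutations avoid the
#'   CDR3 segment, so clone members share their CDR3 exactly and realized
#'   SHM equals planted mutations / sequence length.
#' * `counts` — a wide cell-by-feature table: the nine IGHC subclass
#'   genes (Poisson counts, true isotype at `ighc_count_mean`, others at
#'   `ambient_rate`), ten lineage-marker genes (zero except planted QC
#'   failures), `JCHAIN`, and the `CD19_ADT` antibody-capture signal whose
#'   GC-minus-MBC shift on the per-batch Z scale is calibrated to
#'   `cd19_effect`.
#' * `meta` — barcode, donor, batch, allergy status, mitochondrial
#'   fraction and total RNA count (QC quantities are simulated directly).
#' * `truth_cells` / `truth_clones` — origin labels, true clone ids, true
#'   isotypes and planted structure categories.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `bmpc_sim` with elements `vdj`, `counts`,
#'   `meta`, `truth_cells`, `truth_clones`, `config`.
#' @export
simulate_repertoire <- function(config) {
  validate_sim_config(config)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  plan <- sample_family_plan(config)
  n <- config$n_cells

  # expand plans to cells and build sequences
  n_clones <- nrow(plan)
  cells <- vector("list", n_clones)
  for (i in seq_len(n_clones)) {
    cdr3_nt <- aa_to_nt(plan$cdr3_aa[i])
    v_seq <- plan$v_seq[i]
    germline <- paste0(v_seq, cdr3_nt, plan$j_seq[i])
    cdr3_pos <- seq(nchar(v_seq) + 1, nchar(v_seq) + nchar(cdr3_nt))
    trunk_seq <- mutate_sequence(germline, plan$trunk_mut[i],
                                 protect = cdr3_pos)
    trunk_pos <- which(strsplit(trunk_seq, "")[[1]] !=
                         strsplit(germline, "")[[1]])
    priv <- plan$private_mut[[i]]
    k <- length(priv)
    member_seqs <- vapply(priv, function(m) {
      mutate_sequence(trunk_seq, m, protect = c(cdr3_pos, trunk_pos))
    }, "")
    cells[[i]] <- list(
      clone_id = rep(plan$clone_id[i], k), donor = rep(plan$donor[i], k),
      origin = rep(plan$origin[i], k),
      isotype_gene = rep(plan$isotype_gene[i], k),
      v_call = rep(plan$v_name[i], k), j_call = rep(plan$j_name[i], k),
      junction_aa = rep(plan$cdr3_aa[i], k),
      sequence = member_seqs,
      germline_alignment = rep(germline, k),
      n_mut = plan$trunk_mut[i] + priv
    )
  }
  cols <- names(cells[[1]])
  cells <- tibble::as_tibble(stats::setNames(lapply(cols, function(cl)
    unlist(lapply(cells, `[[`, cl), use.names = FALSE)), cols))
  stopifnot(nrow(cells) == n)
  cells$barcode <- sprintf("CELL%05d-1", seq_len(n))
  cells$shm_true <- 100 * cells$n_mut / nchar(cells$sequence)

  donors <- sprintf("D%02d", seq_len(config$n_donors))
  n_allergic <- round(config$frac_allergic_donors * config$n_donors)
  allergic <- stats::setNames(seq_along(donors) <= n_allergic, donors)
  batches <- paste0("R", ((seq_along(donors) - 1) %% 3) + 1)
  batch_of <- stats::setNames(batches, donors)

  # planted QC failures: disjoint cell sets, one rule each
  n_fail <- sapply(config$qc_fail_rates[c("mito", "rna", "lineage")],
                   function(r) round(r * n))
  fail_idx <- sample.int(n, sum(n_fail))
  mito_fail <- fail_idx[seq_len(n_fail[1])]
  rna_fail <- fail_idx[n_fail[1] + seq_len(n_fail[2])]
  lin_fail <- fail_idx[n_fail[1] + n_fail[2] + seq_len(n_fail[3])]

  mito_fraction <- stats::runif(n, 0, 0.045)
  mito_fraction[mito_fail] <- stats::runif(length(mito_fail), 0.055, 0.25)
  total_rna <- sample(200:4000, n, replace = TRUE)
  if (length(rna_fail)) {
    lo <- rna_fail[seq_len(ceiling(length(rna_fail) / 2))]
    hi <- setdiff(rna_fail, lo)
    total_rna[lo] <- sample(20:199, length(lo), replace = TRUE)
    if (length(hi)) total_rna[hi] <- sample(4001:8000, length(hi),
                                            replace = TRUE)
  }

  # IGHC counts: true isotype vs ambient contamination
  genes <- ighc_genes()
  ighc <- sapply(genes, function(g) {
    lambda <- ifelse(cells$isotype_gene == g, config$ighc_count_mean,
                     config$ambient_rate)
    stats::rpois(n, lambda)
  })

  lin <- matrix(0L, nrow = n, ncol = length(lineage_genes()),
                dimnames = list(NULL, lineage_genes()))
  if (length(lin_fail)) {
    gpick <- sample.int(ncol(lin), length(lin_fail), replace = TRUE)
    lin[cbind(lin_fail, gpick)] <- 1L + stats::rpois(length(lin_fail), 2)
  }

  # CD19 ADT: delta on the log scale calibrated so the GC-minus-MBC
  # difference of per-batch Z-scores equals cd19_effect
  is_gc <- cells$origin == "GC"
  p_gc <- mean(is_gc)
  sigma <- 0.4
  denom <- 1 - config$cd19_effect^2 * p_gc * (1 - p_gc)
  if (denom <= 0)
    stop("simulate_repertoire: cd19_effect too large for the realized ",
         "origin mix (standardized shift unattainable)")
  delta <- config$cd19_effect * sigma / sqrt(denom)
  batch <- unname(batch_of[cells$donor])
  shift <- stats::setNames(stats::rnorm(3, 0, 0.3), paste0("R", 1:3))
  log_cd19 <- 5 + shift[batch] + delta * is_gc + stats::rnorm(n, 0, sigma)
  cd19_adt <- as.integer(round(expm1(log_cd19)))

  jlog <- 3.5 + config$jchain_effect * (!is_gc)
  jchain <- stats::rpois(n, exp(stats::rnorm(n, jlog, 0.3)))

  counts <- tibble::as_tibble(cbind(as.data.frame(ighc), as.data.frame(lin)))
  counts$JCHAIN <- jchain
  counts$CD19_ADT <- cd19_adt
  counts <- tibble::add_column(counts, barcode = cells$barcode, .before = 1)

  meta <- tibble::tibble(
    barcode = cells$barcode, donor = cells$donor, batch = batch,
    allergy_status = unname(allergic[cells$donor]),
    mito_fraction = mito_fraction, total_rna = total_rna
  )

  has_vdj <- stats::runif(n) >= config$vdj_dropout
  vdj <- tibble::tibble(
    cell_id = cells$barcode, v_call = paste0(cells$v_call, "*01"),
    j_call = paste0(cells$j_call, "*01"), junction_aa = cells$junction_aa,
    sequence = cells$sequence, germline_alignment = cells$germline_alignment,
    c_call = cells$isotype_gene
  )[has_vdj, ]

  truth_cells <- tibble::tibble(
    barcode = cells$barcode, origin = cells$origin,
    clone_id = cells$clone_id,
    isotype_subclass = subclass_of_gene(cells$isotype_gene),
    shm_true = cells$shm_true, has_vdj = has_vdj
  )
  truth_clones <- plan |>
    dplyr::mutate(structure = dplyr::case_when(
      size == 1 ~ "singlet",
      origin == "MBC" ~ "isogenic",
      TRUE ~ "heterogenic"
    )) |>
    dplyr::select(dplyr::all_of(c("clone_id", "size", "origin", "donor",
                                  "isotype_gene", "target_shm",
                                  "structure")))

  structure(list(vdj = vdj, counts = counts, meta = meta,
                 truth_cells = truth_cells, truth_clones = truth_clones,
                 config = config),
            class = "bmpc_sim")
}

#' Write a simulated dataset to disk
#'
#' Writes the VDJ table (AIRR TSV), the counts table (TSV), metadata and
#' truth tables, and a JSON run manifest recording the seed and a hash of
#' the configuration.
#'
#' @param sim A `bmpc_sim` object from [simulate_repertoire()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "bmpc_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    vdj = file.path(dir, "vdj.tsv"),
    counts = file.path(dir, "counts.tsv"),
    meta = file.path(dir, "meta.tsv"),
    truth_cells = file.path(dir, "truth_cells.tsv"),
    truth_clones = file.path(dir, "truth_clones.tsv")
  )
  readr::write_tsv(sim$vdj, paths["vdj"])
  readr::write_tsv(sim$counts, paths["counts"])
  readr::write_tsv(sim$meta, paths["meta"])
  readr::write_tsv(sim$truth_cells, paths["truth_cells"])
  readr::write_tsv(sim$truth_clones, paths["truth_clones"])
  manifest <- list(seed = sim$config$seed,
                   config_hash = rlang::hash(unclass(sim$config)),
                   n_cells = sim$config$n_cells,
                   files = as.list(basename(paths)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, manifest = file.path(dir, "manifest.json")))
}
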