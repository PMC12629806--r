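#' Configuration for a synthetic single-cell program cohort
#'
#' Validates and bundles the parameters of the planted-program generator.
#' Programs are non-overlapping gene blocks: `n_shared_programs` blocks occur
#' in every sample, `n_private_programs_per_sample` additional blocks are
#' private to each sample. Every cell is dominated by exactly one program of
#' its sample; its program genes receive `Poisson(signal_strength)` extra
#' counts on top of the `Poisson(noise_rate)` background.
#'
#' @param n_samples,cells_per_sample,n_genes Cohort dimensions.
#' @param n_shared_programs Programs shared by all samples.
#' @param n_private_programs_per_sample Programs private to each sample.
#' @param program_size Genes per planted program.
#' @param signal_strength Mean added counts on program genes of assigned
#'   cells.
#' @param noise_rate Poisson background mean for all genes.
#' @param active_fraction Fraction of a sample's cells dominated by each
#'   program; the default spreads cells evenly over the sample's programs.
#' @param seed Integer seed.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 6, cells_per_sample = 200,
                          n_genes = 1000, n_shared_programs = 3,
                          n_private_programs_per_sample = 0,
                          program_size = 50, signal_strength = 5,
                          noise_rate = 0.2, active_fraction = NULL,
                          seed = 1L) {
  n_prog_sample <- n_shared_programs + n_private_programs_per_sample
  if (n_prog_sample < 1L) abort("config error: at least one program per sample required")
  needed <- (n_shared_programs +
               n_private_programs_per_sample * n_samples) * program_size
  if (needed > n_genes) {
    abort(sprintf(
      "config error: programs need %d genes but n_genes = %d", needed, n_genes))
  }
  if (signal_strength < 0 || noise_rate < 0) {
    abort("config error: signal_strength and noise_rate must be nonnegative")
  }
  af <- active_fraction %||% (1 / n_prog_sample)
  if (af <= 0 || af > 1) abort("config error: active_fraction must be in (0, 1]")
  structure(list(
    n_samples = n_samples, cells_per_sample = cells_per_sample,
    n_genes = n_genes, n_shared_programs = n_shared_programs,
    n_private_programs_per_sample = n_private_programs_per_sample,
    program_size = program_size, signal_strength = signal_strength,
    noise_rate = noise_rate, active_fraction = af, seed = as.integer(seed)),
    class = "cohort_config")
}

#' Generate a synthetic cohort with planted gene programs
#'
#' Counts are `Poisson(noise_rate)` background plus `Poisson(signal_strength)`
#' on the planted program genes of each cell's assigned program. Sample-level
#' phenotypes (response R/NR, timepoint pre/post, arm D / D+T) are assigned
#' deterministically by alternating over samples, mirroring sample-level
#' clinical labels.
#'
#' @param config A [cohort_config()].
#' @return List with `counts` (sparse integer matrix, cells x genes),
#'   `cells` (tibble: cell, sample, response, timepoint, arm, program) and
#'   `truth` (list: `shared_program_genes`, `private_program_genes`,
#'   `assignment`).
#' @export
generate_program_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  n_cells <- config$n_samples * config$cells_per_sample

  # carve disjoint gene blocks: shared first, then per-sample private
  cursor <- 0L
  take <- function(n) {
    out <- genes[cursor + seq_len(n)]
    cursor <<- cursor + n
    out
  }
  shared <- lapply(seq_len(config$n_shared_programs),
                   function(i) take(config$program_size))
  names(shared) <- paste0("shared_", seq_along(shared))
  private <- lapply(seq_len(config$n_samples), function(s) {
    ps <- lapply(seq_len(config$n_private_programs_per_sample),
                 function(i) take(config$program_size))
    if (length(ps)) names(ps) <- paste0("private_s", s, "_", seq_along(ps))
    ps
  })

  cells <- character(0); samples <- character(0); programs <- character(0)
  per_prog <- max(1L, floor(config$active_fraction * config$cells_per_sample))
  for (s in seq_len(config$n_samples)) {
    prog_names <- c(names(shared), names(private[[s]]))
    # equal blocks per program, leftover cells cycled round-robin
    assign <- rep(prog_names, each = per_prog)
    if (length(assign) < config$cells_per_sample) {
      assign <- c(assign, rep_len(prog_names,
                                  config$cells_per_sample - length(assign)))
    }
    assign <- assign[seq_len(config$cells_per_sample)]
    cells <- c(cells, sprintf("s%d_c%03d", s, seq_len(config$cells_per_sample)))
    samples <- c(samples, rep(paste0("s", s), config$cells_per_sample))
    programs <- c(programs, assign)
  }

  counts <- matrix(rpois(n_cells * config$n_genes, config$noise_rate),
                   nrow = n_cells, dimnames = list(cells, genes))
  prog_genes <- c(shared, do.call(c, private))
  for (p in names(prog_genes)) {
    rows <- which(programs == p)
    if (length(rows) && config$signal_strength > 0) {
      counts[rows, prog_genes[[p]]] <-
        counts[rows, prog_genes[[p]]] +
        rpois(length(rows) * config$program_size, config$signal_strength)
    }
  }

  sample_ids <- paste0("s", seq_len(config$n_samples))
  meta <- tibble::tibble(
    cell = cells, sample = samples,
    response = rep_len(c("R", "NR"), config$n_samples)[match(samples, sample_ids)],
    timepoint = rep_len(c("pre", "post"), config$n_samples)[match(samples, sample_ids)],
    arm = rep_len(c("D", "D+T"), config$n_samples)[match(samples, sample_ids)],
    program = programs)

  list(counts = Matrix(counts, sparse = TRUE),
       cells = meta,
       truth = list(shared_program_genes = shared,
                    private_program_genes = private,
                    assignment = setNames(programs, cells)))
}

#' Generate synthetic TCR contigs with planted clonal structure
#'
#' Each planted clone gets a V gene and a random length-14 CDR3 ancestor over
#' the 20 amino-acid alphabet; member cells carry at most one substitution
#' (probability `mutation_rate` per position, capped at one position per
#' sequence), which keeps within-clone pairwise similarity at or above
#' 1 - 2/14 ~ 0.857, safely over the 0.85 clustering threshold. Ancestors of
#' distinct clones are rejection-sampled to stay below 0.7 similarity when
#' they share a V gene.
#'
#' @param n_cells Total cells; must equal `sum(expansion_profile)`.
#' @param expansion_profile Named integer vector, clone -> cell count.
#' @param v_genes Candidate V genes (sampled per clone).
#' @param mutation_rate Per-position substitution probability within a clone.
#' @param seed Integer seed.
#' @return Tibble with `barcode`, `v_gene`, `cdr3` plus a `clone` truth
#'   column.
#' @export
generate_tcr_contigs <- function(n_cells, expansion_profile,
                                 v_genes = paste0("TRBV", 1:6),
                                 mutation_rate = 0.02, seed = 1L) {
  if (sum(expansion_profile) != n_cells) {
    abort(sprintf("expansion_profile sums to %d but n_cells = %d",
                  sum(expansion_profile), n_cells))
  }
  if (is.null(names(expansion_profile))) {
    names(expansion_profile) <- paste0("clone", seq_along(expansion_profile))
  }
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(seed)
  clone_v <- sample(v_genes, length(expansion_profile), replace = TRUE)
  ancestors <- character(0)
  for (i in seq_along(expansion_profile)) {
    repeat {
      cand <- paste(sample(aa, 14, replace = TRUE), collapse = "")
      same_v <- ancestors[clone_v[seq_along(ancestors)] == clone_v[i]]
      ok <- length(same_v) == 0 ||
        all(normalized_similarity(rep(cand, length(same_v)), same_v) < 0.7)
      if (ok) break
    }
    ancestors <- c(ancestors, cand)
  }
  rows <- lapply(seq_along(expansion_profile), function(i) {
    n <- expansion_profile[i]
    cdr3 <- vapply(seq_len(n), function(j) {
      s <- strsplit(ancestors[i], "")[[1]]
      if (rbinom(1, 1, min(1, mutation_rate * 14)) == 1L) {
        pos <- sample(14, 1)
        s[pos] <- sample(setdiff(aa, s[pos]), 1)
      }
      paste(s, collapse = "")
    }, character(1))
    tibble::tibble(clone = names(expansion_profile)[i],
                   v_gene = clone_v[i], cdr3 = cdr3)
  })
  out <- dplyr::bind_rows(rows)
  out$barcode <- sprintf("bc%04d", seq_len(nrow(out)))
  out[, c("barcode", "v_gene", "cdr3", "clone")]
}

#' Generate a synthetic cell-to-cell transition matrix
#'
#' Row weights are independent `Gamma(1, bias)` draws where
#' `bias = transition_bias[from_subset, to_subset]` (default 1 for pairs not
#' listed), then rows are normalized to sum to 1; expected mass from subset a
#' into subset b is therefore proportional to the bias times the target
#' subset's size.
#'
#' @param n_cells Number of cells; must equal `length(subset_labels)`.
#' @param subset_labels Character vector of per-cell subset labels.
#' @param transition_bias Data frame with columns `from`, `to`, `bias`
#'   (nonnegative); missing pairs default to 1.
#' @param seed Integer seed.
#' @return List with `matrix` (row-stochastic, cell names on both axes) and
#'   `cells` (tibble: cell, subset).
#' @export
generate_transition_matrix <- function(n_cells, subset_labels,
                                       transition_bias = NULL, seed = 1L) {
  stopifnot(length(subset_labels) == n_cells)
  if (!is.null(transition_bias) && any(transition_bias$bias < 0)) {
    abort("transition bias values must be nonnegative")
  }
  set.seed(seed)
  cells <- sprintf("cell%04d", seq_len(n_cells))
  bias <- matrix(1, n_cells, n_cells)
  if (!is.null(transition_bias)) {
    for (r in seq_len(nrow(transition_bias))) {
      bias[subset_labels == transition_bias$from[r],
           subset_labels == transition_bias$to[r]] <- transition_bias$bias[r]
    }
  }
  m <- matrix(stats::rgamma(n_cells^2, shape = 1), n_cells) * bias
  dimnames(m) <- list(cells, cells)
  list(matrix = normalize_rows(m),
       cells = tibble::tibble(cell = cells, subset = subset_labels))
}

#' Generate synthetic bulk immunotherapy cohorts
#'
#' Emulates a multi-study bulk RNA compendium for response prediction: each
#' cohort is a genes x samples Gaussian expression table with a planted
#' immune signature and a planted senescence-like program. Set-gene
#' expression carries a sample-level latent activity (standard normal) that
#' is shifted upward in responders by `effect_of_senescence` /
#' `effect_of_immune` pooled SDs; stromal score and tumor purity are
#' uninformative standard-normal features.
#'
#' @param n_cohorts Number of cohorts (studies).
#' @param samples_per_cohort Samples per cohort (>= 30 to pass downstream
#'   cohort filters).
#' @param n_genes Genes per cohort (default 12000, above the 10k filter).
#' @param effect_of_senescence Responder shift of the senescence latent, in
#'   pooled SDs.
#' @param effect_of_immune Responder shift of the immune latent (default
#'   0.8, a moderately predictive baseline signature).
#' @param set_size Genes per planted signature (default 30).
#' @param response_rate Responder fraction per cohort (default 0.4).
#' @param seed Integer seed.
#' @return List with `cohorts` (named list; each has `expression`,
#'   `samples`) and `gene_sets` (`immune`, `senescence`).
#' @export
generate_bulk_cohorts <- function(n_cohorts = 8, samples_per_cohort = 60,
                                  n_genes = 12000, effect_of_senescence = 2,
                                  effect_of_immune = 0.8, set_size = 30,
                                  response_rate = 0.4, seed = 1L) {
  set.seed(seed)
  genes <- sprintf("bg%05d", seq_len(n_genes))
  immune <- genes[seq_len(set_size)]
  senescence <- genes[set_size + seq_len(set_size)]
  baseline <- rnorm(n_genes, mean = 5, sd = 2)

  cohorts <- lapply(seq_len(n_cohorts), function(ci) {
    n <- samples_per_cohort
    samples <- sprintf("st%d_s%02d", ci, seq_len(n))
    resp <- ifelse(seq_len(n) <= round(response_rate * n),
                   "responder", "non-responder")
    lat_imm <- rnorm(n) + effect_of_immune * (resp == "responder")
    lat_sen <- rnorm(n) + effect_of_senescence * (resp == "responder")
    expr <- matrix(rnorm(n_genes * n, baseline), n_genes,
                   dimnames = list(genes, samples))
    expr[immune, ] <- expr[immune, ] + rep(lat_imm, each = set_size)
    expr[senescence, ] <- expr[senescence, ] + rep(lat_sen, each = set_size)
    list(expression = expr,
         samples = tibble::tibble(
           sample = samples, response = resp,
           stromal_score = rnorm(n), tumor_purity = rnorm(n)))
  })
  names(cohorts) <- paste0("study", seq_len(n_cohorts))
  list(cohorts = cohorts,
       gene_sets = list(immune = immune, senescence = senescence))
}
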