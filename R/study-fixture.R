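#' Generate a study-like synthetic phylogeographic data set
#'
#' Emulates the sampling design of a two-clade mitochondrial phylogeography:
#' two clades split deeply, each split again into two subgroups, each
#' subgroup having undergone a recent sudden expansion; samples are scattered
#' over many small populations (1-15 individuals) nested in the four
#' subgroups.  Cross-subgroup divergence is controlled by stem branches whose
#' mutational lengths are chosen so that between-clade distance is about
#' 3 percent and between-subgroup distance 1.5-2 percent of a 1,140-bp
#' sequence, with transition-biased substitution (kappa = 5.33) throughout.
#' With \code{structured = FALSE} a single panmictic constant-size pool with
#' the same population partitioning is produced (negative control).
#'
#' @param seed integer seed; output is byte-identical for a given seed.
#' @param dir output directory (created if needed); NULL returns the objects
#'   without writing files.
#' @param n_per_subgroup sample sizes of the four subgroups.
#' @param structured generate the hierarchical history (TRUE) or a panmictic
#'   pool (FALSE).
#' @param L sites.
#' @param kappa transition bias.
#' @return list with \code{alignment}, \code{popmap}, \code{params}, and
#'   (when \code{dir} given) \code{files} (fasta, popmap, json sidecar).
#' @export
make_study_like_dataset <- function(seed = 1L, dir = NULL,
                                    n_per_subgroup = c(E1 = 40L, E2 = 12L,
                                                       W1 = 16L, W2 = 24L),
                                    structured = TRUE, L = 1140L,
                                    kappa = 5.33) {
  params <- list(seed = seed, n_per_subgroup = as.list(n_per_subgroup),
                 structured = structured, L = L, kappa = kappa,
                 expansion = list(theta0 = 1, theta1 = 50, tau = 5),
                 stem_subgroup_mutations = 8, stem_clade_mutations = 6)
  out <- with_seed(seed, {
    subgroups <- names(n_per_subgroup)
    clade_of <- c(E1 = "E", E2 = "E", W1 = "W", W2 = "W")[subgroups]
    root <- sample(VALID_BASES, L, replace = TRUE)
    seqs <- character(0)
    labels <- character(0)
    sub_of <- character(0)
    if (structured) {
      model <- demography_model("sudden_expansion", theta0 = 1, theta1 = 50,
                                tau = 5)
      clade_anc <- list()
      for (cl in unique(clade_of)) {
        clade_anc[[cl]] <- mutate_lineage(root, rpois(1L, params$stem_clade_mutations),
                                          kappa, L)
      }
      for (sg in subgroups) {
        anc <- mutate_lineage(clade_anc[[clade_of[[sg]]]],
                              rpois(1L, params$stem_subgroup_mutations),
                              kappa, L)
        cfg <- sim_config(n = n_per_subgroup[[sg]], L = L, kappa = kappa)
        tree <- simulate_genealogy(model, cfg)
        aln <- mutate_sequences(tree, cfg, root_seq = anc)
        ids <- paste0(sg, "_", seq_along(aln$ids))
        seqs <- c(seqs, setNames(unname(aln$seq), ids))
        sub_of <- c(sub_of, setNames(rep(sg, length(ids)), ids))
      }
    } else {
      n_tot <- sum(n_per_subgroup)
      model <- demography_model("constant", theta = 10)
      cfg <- sim_config(n = n_tot, L = L, kappa = kappa)
      tree <- simulate_genealogy(model, cfg)
      aln <- mutate_sequences(tree, cfg, root_seq = root)
      k <- 0L
      for (sg in subgroups) {
        ids <- paste0(sg, "_", seq_len(n_per_subgroup[[sg]]))
        seqs <- c(seqs, setNames(unname(aln$seq[k + seq_len(n_per_subgroup[[sg]])]), ids))
        sub_of <- c(sub_of, setNames(rep(sg, length(ids)), ids))
        k <- k + n_per_subgroup[[sg]]
      }
    }
    # scatter samples of each subgroup over small populations (1-4 samples)
    popmap <- NULL
    pop_counter <- 0L
    for (sg in subgroups) {
      ids <- names(sub_of)[sub_of == sg]
      remaining <- ids
      while (length(remaining)) {
        pop_counter <- pop_counter + 1L
        take <- min(length(remaining), sample.int(4L, 1L))
        popmap <- rbind(popmap, data.frame(
          sample_id = remaining[seq_len(take)],
          population_id = sprintf("p%02d", pop_counter),
          group_id = sg, stringsAsFactors = FALSE))
        remaining <- remaining[-seq_len(take)]
      }
    }
    aln <- alignment(seqs)
    list(alignment = aln, popmap = popmap)
  })
  out$params <- params
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fa <- file.path(dir, "study_like.fasta")
    tsv <- file.path(dir, "study_like_popmap.tsv")
    js <- file.path(dir, "study_like_params.json")
    write_alignment(out$alignment, fa)
    write.table(out$popmap, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(params, js, auto_unbox = TRUE, pretty = TRUE)
    out$files <- c(fasta = fa, popmap = tsv, params = js)
  }
  out
}
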