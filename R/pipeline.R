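#' Run the full phylogeographic analysis pipeline
#'
#' Orchestrates alignment reading, haplotype collapsing, site classification,
#' diversity summaries, the median-joining network, AMOVA per grouping
#' scheme, pairwise Fst, and per-group demography (mismatch fit, neutrality
#' tests, expansion dating), writing TSV/JSON/GraphML reports plus a run log
#' with the seed and per-stage timings.  Every referenced scheme and
#' population is validated before any computation starts, so a bad
#' configuration fails immediately.
#'
#' @param config named list (or path to a YAML file with these keys):
#'   \describe{
#'     \item{fasta, popmap}{input paths (required).}
#'     \item{out_dir}{output directory (required; created).}
#'     \item{schemes}{named list of population -> group maps (optional;
#'       the popmap's own group column is always analysed as scheme
#'       "popmap_groups").}
#'     \item{n_perm, n_boot, n_sim}{permutation / bootstrap / simulation
#'       counts (defaults 1000, 200, 1000).}
#'     \item{calibration}{list with clade_divergence_k2p,
#'       divergence_time_years, L, generation_years (optional; enables
#'       dating).}
#'     \item{seed}{integer; generated and recorded when absent.}
#'     \item{min_group_n}{smallest group analysed for demography (default 4).}
#'   }
#' @return list of stage results, invisibly; files under \code{out_dir}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (key in c("fasta", "popmap", "out_dir"))
    if (is.null(config[[key]])) stop("config is missing '", key, "'")
  n_perm <- config$n_perm %||% 1000L
  n_boot <- config$n_boot %||% 200L
  n_sim <- config$n_sim %||% 1000L
  seed <- config$seed %||% sample.int(2^30, 1L)
  min_group_n <- config$min_group_n %||% 4L

  inp <- read_alignment(config$fasta, config$popmap)
  aln <- inp$alignment
  pm <- inp$popmap

  # fail fast: every scheme must cover every population before any stage runs
  schemes <- list()
  if (!is.null(config$schemes)) {
    for (nm in names(config$schemes)) {
      mapping <- unlist(config$schemes[[nm]])
      missing <- setdiff(unique(pm$population_id), names(mapping))
      if (length(missing))
        stop("scheme '", nm, "' does not assign population(s): ",
             paste(missing, collapse = ", "))
      schemes[[nm]] <- grouping_scheme(nm, mapping)
    }
  }
  cal <- if (!is.null(config$calibration)) {
    cc <- config$calibration
    rate_calibration(cc$clade_divergence_k2p, cc$divergence_time_years,
                     cc$L %||% aln$L, cc$generation_years %||% 1)
  } else NULL

  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log <- list(seed = seed, n_perm = n_perm, n_boot = n_boot, n_sim = n_sim,
              n_samples = length(aln$ids), L = aln$L,
              package_version = as.character(utils::packageVersion("mitopop")),
              stages = list())
  results <- list()
  stage_seeds <- with_seed(seed, sample.int(2^30, 8L))
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    log$stages[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }

  results$haplotypes <- timed("collapse", collapse_haplotypes(aln, pm))
  results$sites <- timed("sites", suppressMessages(classify_sites(results$haplotypes)))
  results$diversity <- timed("diversity", diversity_report(aln, pm))
  write.table(results$diversity, file.path(out_dir, "diversity.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  results$network <- timed("network", median_joining(results$haplotypes))
  export_network(results$network, file.path(out_dir, "network.graphml"))
  export_network(results$network, file.path(out_dir, "network.dot"))
  export_network(results$network, file.path(out_dir, "network_edges.tsv"))

  dm_raw <- timed("distances", distance_matrix(aln, model = "raw"))
  results$amova <- list()
  all_schemes <- c(list(popmap_groups = NULL), schemes)
  for (i in seq_along(all_schemes)) {
    nm <- names(all_schemes)[i]
    res <- timed(paste0("amova_", nm),
                 amova(dm_raw, pm, scheme = all_schemes[[i]],
                       n_perm = n_perm, seed = stage_seeds[1L] + i))
    results$amova[[nm]] <- res
    write_structure_report(res, file.path(out_dir, paste0("amova_", nm, ".tsv")))
  }
  results$fst <- timed("fst", pairwise_fst(dm_raw, pm, n_perm = n_perm,
                                           seed = stage_seeds[2L]))
  write_structure_report(results$fst, file.path(out_dir, "fst.tsv"))

  results$demography <- timed("demography",
                              demography_report(aln, pm, cal = cal,
                                                n_boot = n_boot, n_sim = n_sim,
                                                seed = stage_seeds[3L],
                                                min_n = min_group_n))
  if (!is.null(results$demography))
    write.table(results$demography, file.path(out_dir, "demography.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  for (g in unique(pm$group_id)) {
    ids <- pm$sample_id[pm$group_id == g]
    if (length(ids) < 2L) next
    h <- mismatch_histogram(subset_alignment(aln, ids))
    write.table(data.frame(differences = h$classes, count = h$counts,
                           freq = h$freq),
                file.path(out_dir, paste0("mismatch_", g, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  summary_json <- list(
    n_samples = length(aln$ids),
    n_haplotypes = length(results$haplotypes$seq),
    conserved_sites = results$sites$conserved,
    variable_sites = results$sites$variable,
    ts_tv = results$sites$ts_tv,
    total_Hd = results$diversity$Hd[results$diversity$level == "total"],
    total_pi = results$diversity$pi[results$diversity$level == "total"],
    amova = lapply(results$amova, function(a)
      list(phi = as.list(a$phi), p = as.list(a$p), pct = as.list(a$pct))),
    network_cost = network_cost(results$network))
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
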