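# Config-driven orchestration of all analysis stages.

#' Read a pipeline run configuration (YAML)
#'
#' The configuration is a declarative YAML document with an `out_dir`, an
#' optional global `seed`, and one block per stage (`seqstats`, `hapnet`,
#' `demography`, `clusterpost`, `nichetest`, `colourindex`), each carrying
#' `enabled`, its input paths and stage parameters. See
#' [run_pipeline()] for the recognised fields.
#'
#' @param file YAML path.
#' @return A list of class `hm_runconfig`.
#' @export
read_run_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  structure(cfg, class = "hm_runconfig")
}

.stage_enabled <- function(cfg, stage) {
  isTRUE(cfg[[stage]][["enabled"]] %||% FALSE)
}

# Pre-flight validation: collect every missing input across enabled stages
# and report them all at once.
.preflight <- function(cfg) {
  problems <- character(0)
  need_file <- function(stage, field) {
    p <- cfg[[stage]][[field]]
    if (is.null(p)) {
      problems <<- c(problems, sprintf("stage '%s': missing required input '%s'", stage, field))
    } else if (!file.exists(p)) {
      problems <<- c(problems, sprintf("stage '%s': file not found: %s", stage, p))
    }
  }
  if (.stage_enabled(cfg, "seqstats") || .stage_enabled(cfg, "hapnet")) {
    need_file("seqstats", "alignment")
  }
  if (.stage_enabled(cfg, "demography")) {
    need_file("demography", "contemporary")
    need_file("demography", "historical")
  }
  if (.stage_enabled(cfg, "clusterpost")) need_file("clusterpost", "genotypes")
  if (.stage_enabled(cfg, "nichetest")) {
    need_file("nichetest", "occurrences")
    need_file("nichetest", "background")
  }
  if (.stage_enabled(cfg, "colourindex")) need_file("colourindex", "traits")
  if (length(problems))
    .stopf("pipeline pre-flight failed:\n%s", paste("  -", problems, collapse = "\n"))
  invisible(TRUE)
}

.log_stage <- function(stage, expr) {
  t0 <- Sys.time()
  message(sprintf("[%s] starting", stage))
  res <- force(expr)
  message(sprintf("[%s] done in %.2fs", stage,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order (seqstats before
#' hapnet; the remaining stages are independent), writes per-stage outputs
#' under `out_dir`, and produces both a machine-readable JSON summary and
#' a human-readable text report. Warnings raised by stages are collected
#' into the report. No stage mutates another stage's inputs.
#'
#' @param config an `hm_runconfig` (see [read_run_config()]) or a plain
#'   list with the same structure.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @param seed global seed override applied to every stage seed.
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- unclass(config)
  out_dir <- out_dir %||% cfg$out_dir %||% .stopf("no out_dir configured")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(seed)) cfg$seed <- seed
  gseed <- cfg$seed %||% 1L
  .preflight(cfg)
  summary <- list(schema_version = "1.0", seed = gseed, stages = list())
  report <- c("hummintro pipeline report", "=========================")
  warnings_seen <- character(0)
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  aln <- NULL
  if (.stage_enabled(cfg, "seqstats")) {
    sc <- cfg$seqstats
    aln <- read_alignment(sc$alignment, sc$popmap)
    res <- .log_stage("seqstats", collect({
      population_summary(aln,
                         n_replicates = sc$n_replicates %||% 1000,
                         n_bootstrap = sc$n_bootstrap %||% 1000,
                         seed = gseed,
                         file = file.path(out_dir, "seqstats.tsv"))
    }))
    summary$stages$seqstats <- res
    report <- c(report, "", "[seqstats] per-population summary written to seqstats.tsv")
  }

  if (.stage_enabled(cfg, "hapnet")) {
    hc <- cfg$hapnet
    if (is.null(aln)) aln <- read_alignment(cfg$seqstats$alignment, cfg$seqstats$popmap)
    net <- .log_stage("hapnet", collect({
      haps <- collapse_haplotypes(aln)
      median_joining(haps, epsilon = hc$epsilon %||% 0)
    }))
    write_network_gml(net, file.path(out_dir, "network.gml"))
    write_network_edgelist(net, file.path(out_dir, "network_edges.tsv"))
    summary$stages$hapnet <- list(nodes = length(net$nodes),
                                  medians = sum(net$is_median),
                                  edges = nrow(net$edges), cost = net$cost)
    report <- c(report, "", sprintf("[hapnet] %d nodes (%d median vectors), %d edges, cost %g",
                                    length(net$nodes), sum(net$is_median),
                                    nrow(net$edges), net$cost))
  }

  if (.stage_enabled(cfg, "demography")) {
    dc <- cfg$demography
    res <- .log_stage("demography", collect({
      contemp <- read_migration_matrix(dc$contemporary)
      hist <- read_migration_matrix(dc$historical)
      tabs <- migration_tables(contemp, hist,
                               theta = dc$theta, mu = dc$mu %||% 5e-4)
      cmp <- compare_migration_eras(tabs, n_perm = dc$n_perm %||% 5000,
                                    seed = gseed,
                                    mode = dc$mode %||% "migrate")
      gens <- lapply(dc$generation_times %||% list(list(a = 2, s = 0.30),
                                                   list(a = 2, s = 0.52)),
                     function(g) generation_time(g$a, g$s)$T)
      list(mantel_r = cmp$mantel$r, mantel_p = cmp$mantel$p,
           era_ratio = cmp$era_ratio, generation_times = unlist(gens))
    }))
    summary$stages$demography <- list(mantel_r = res$mantel_r,
                                      mantel_p = res$mantel_p,
                                      generation_times = res$generation_times)
    write.csv(res$era_ratio, file.path(out_dir, "era_ratios.csv"))
    report <- c(report, "", sprintf("[demography] Mantel r = %.3f (p = %.3g); T = %s years",
                                    res$mantel_r, res$mantel_p,
                                    paste(round(res$generation_times, 2), collapse = ", ")))
  }

  if (.stage_enabled(cfg, "clusterpost")) {
    cc <- cfg$clusterpost
    res <- .log_stage("clusterpost", collect({
      gm <- read_genotypes(cc$genotypes)
      pca <- genotype_pca(gm, n_axes = cc$n_axes %||% 4)
      out <- list(pca_explained = pca$explained[seq_len(min(4, length(pca$explained)))])
      write.csv(data.frame(id = rownames(pca$scores), pop = pca$pop, pca$scores),
                file.path(out_dir, "genotype_pca.csv"), row.names = FALSE)
      if (!is.null(cc$lnp_table)) {
        lt <- read.delim(cc$lnp_table)
        dk <- evanno_delta_k(lt)
        write.table(dk$summary, file.path(out_dir, "deltaK.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        out$best_K <- dk$best_K
      }
      out
    }))
    summary$stages$clusterpost <- res
    report <- c(report, "", sprintf("[clusterpost] PCA axes 1-4 explain %s%%%s",
                                    paste(round(100 * res$pca_explained, 1), collapse = "/"),
                                    if (!is.null(res$best_K)) sprintf("; Evanno best K = %d", res$best_K) else ""))
  }

  if (.stage_enabled(cfg, "nichetest")) {
    nc <- cfg$nichetest
    res <- .log_stage("nichetest", collect({
      occ <- read_climate_table(nc$occurrences)
      bg <- read_climate_table(nc$background)
      groups <- sort(unique(occ$group))
      vars <- nc$vars %||% grep("^bio", names(occ), value = TRUE)
      pairs <- combn(groups, 2L)
      all_rows <- list()
      for (i in seq_len(ncol(pairs))) {
        gA <- pairs[1L, i]; gB <- pairs[2L, i]
        nt <- niche_divergence_test(occ[occ$group == gA, ], bg[bg$group == gA, ],
                                    occ[occ$group == gB, ], bg[bg$group == gB, ],
                                    vars = vars,
                                    n_axes = nc$n_axes %||% 4,
                                    n_rep = nc$n_rep %||% 1000,
                                    fraction = nc$fraction %||% 0.75,
                                    alpha = nc$alpha %||% 0.05,
                                    seed = gseed + i)
        nt$pair <- paste(gA, "vs", gB)
        all_rows[[i]] <- as.data.frame(nt)
      }
      elev <- elevation_comparison(occ$elevation, occ$group)
      list(table = do.call(rbind, all_rows),
           kruskal_h = unname(elev$kruskal$statistic),
           kruskal_p = elev$kruskal$p.value)
    }))
    write.table(res$table, file.path(out_dir, "nichetest.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    summary$stages$nichetest <- list(
      classifications = res$table$classification,
      kruskal_h = res$kruskal_h, kruskal_p = res$kruskal_p)
    report <- c(report, "", sprintf("[nichetest] %d pairwise axis tests; Kruskal-Wallis H = %.2f (p = %.3g)",
                                    nrow(res$table), res$kruskal_h, res$kruskal_p))
  }

  if (.stage_enabled(cfg, "colourindex")) {
    pc <- cfg$colourindex
    res <- .log_stage("colourindex", collect({
      tr <- read_plumage_table(pc$traits)
      scored <- score_plumage_table(tr)
      write_plumage_table(scored, file.path(out_dir, "plumage_scored.csv"))
      cp <- cline_profile(scored, n_bins = pc$n_bins %||% 8)
      write.csv(cp$index, file.path(out_dir, "plumage_cline.csv"), row.names = FALSE)
      list(index_range = range(scored$index),
           bin_means = cp$index$mean,
           n_specimens = nrow(scored))
    }))
    summary$stages$colourindex <- res
    report <- c(report, "", sprintf("[colourindex] index range %d-%d across %d specimens",
                                    res$index_range[1L], res$index_range[2L],
                                    res$n_specimens))
  }

  if (length(warnings_seen)) {
    summary$warnings <- warnings_seen
    report <- c(report, "", "Warnings:", paste(" -", warnings_seen))
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(report, file.path(out_dir, "report.txt"))
  invisible(summary)
}
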