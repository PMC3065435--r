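#' Pipeline configuration
#'
#' Collects every knob of the two-step module discovery run. Inputs may be
#' file paths (labelled TSV, see [read_matrix()]) or in-memory matrices.
#'
#' @param map map matrix ([map_matrix()] or TSV path).
#' @param mirna_expr,mrna_expr matched expression inputs
#'   ([expression_matrix()] or TSV paths).
#' @param mrna_method,mirna_method clustering route per side: `"both"`
#'   (run unguided and guided, keep the one with higher best Pr_enrich;
#'   unguided wins ties as the simpler method), `"unguided"`, or
#'   `"guided"`.
#' @param algorithm `"pam"` (default) or `"hclust"`.
#' @param linkage linkage for the hclust comparator.
#' @param K_mrna,K_mirna integer grids of cluster counts to sweep.
#' @param node_size,n_trees,num_cov,row_bootstrap forest parameters (see
#'   [forest_proximity()]); `num_cov = NULL` means `round(sqrt(X))`.
#' @param B bootstrap replicates for both bootstrap tests.
#' @param alpha significance level of both bootstrap tests.
#' @param direction,alpha_level pair-association test settings (see
#'   [fit_pair()]).
#' @param majority_threshold targeting fraction every module miRNA must
#'   strictly exceed.
#' @param seed master seed; stage seeds are derived from it.
#' @param out_dir directory for artefacts (`NULL`: nothing is written).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(map, mirna_expr, mrna_expr,
                            mrna_method = c("both", "unguided", "guided"),
                            mirna_method = c("unguided", "both", "guided"),
                            algorithm = "pam", linkage = "average",
                            K_mrna, K_mirna,
                            node_size = 5L, n_trees = 100L, num_cov = NULL,
                            row_bootstrap = FALSE,
                            B = 100L, alpha = 0.05,
                            direction = "negative", alpha_level = 0.05,
                            majority_threshold = 0.5, seed = 1L,
                            out_dir = NULL) {
  cfg <- list(map = map, mirna_expr = mirna_expr, mrna_expr = mrna_expr,
              mrna_method = match.arg(mrna_method),
              mirna_method = match.arg(mirna_method),
              algorithm = algorithm, linkage = linkage,
              K_mrna = as.integer(K_mrna), K_mirna = as.integer(K_mirna),
              node_size = as.integer(node_size),
              n_trees = as.integer(n_trees), num_cov = num_cov,
              row_bootstrap = isTRUE(row_bootstrap),
              B = as.integer(B), alpha = alpha, direction = direction,
              alpha_level = alpha_level,
              majority_threshold = majority_threshold,
              seed = as.integer(seed), out_dir = out_dir)
  if (length(cfg$K_mrna) == 0L || length(cfg$K_mirna) == 0L) {
    abort("K grids must be non-empty")
  }
  structure(cfg, class = "pipeline_config")
}

load_input <- function(x, kind, what) {
  if (is.character(x)) {
    if (!file.exists(x)) abort(paste0("missing input file for ", what, ": ", x))
    read_matrix(x, kind)
  } else if (kind == "map" && inherits(x, "map_matrix")) {
    x
  } else if (kind == "expression" && inherits(x, "expr_matrix")) {
    x
  } else {
    abort(paste0("unusable input for ", what,
                 ": give a path or a ", kind, " matrix"))
  }
}

# Sweep one side under the requested route(s) and pick the better one.
sweep_side <- function(methods, d_un, d_gd, map_profiles, K_grid, cfg,
                       keep_singletons, seed, side) {
  seeds <- derive_seeds(seed, 2L)
  sweeps <- list()
  if (methods %in% c("both", "unguided")) {
    sweeps$unguided <- sweep_k(d_un, map_profiles, K_grid, B = cfg$B,
                               alpha = cfg$alpha,
                               keep_singletons = keep_singletons,
                               algorithm = cfg$algorithm,
                               linkage = cfg$linkage, method = "unguided",
                               seed = seeds[1L])
  }
  if (methods %in% c("both", "guided")) {
    sweeps$guided <- sweep_k(d_gd(), map_profiles, K_grid, B = cfg$B,
                             alpha = cfg$alpha,
                             keep_singletons = keep_singletons,
                             algorithm = cfg$algorithm,
                             linkage = cfg$linkage, method = "guided",
                             seed = seeds[2L])
  }
  best <- vapply(sweeps, function(s) max(s$table$pr_enrich), numeric(1L))
  # unguided wins ties: it is the simpler of the two methods
  chosen <- if ("unguided" %in% names(sweeps) &&
                best[["unguided"]] >= max(best)) "unguided" else "guided"
  message(sprintf("[%s] chose %s clustering (best Pr_enrich: %s)", side,
                  chosen,
                  paste(sprintf("%s = %.3f", names(best), best),
                        collapse = ", ")))
  list(sweeps = sweeps, chosen = chosen, sweep = sweeps[[chosen]])
}

#' Run the full two-step module-identification pipeline
#'
#' Aligns the inputs, sweeps K on the mRNA side (unguided and/or guided,
#' keeping the route with the higher best Pr_enrich; ties go to unguided),
#' does the same on the miRNA side (on the transposed map, retaining
#' singleton miRNA clusters untested), then evaluates every pairing of
#' retained clusters for association and reports potentially regulatory
#' modules. When `config$out_dir` is set, all stage artefacts and a run
#' manifest are written there; outputs are byte-deterministic for a fixed
#' config and seed.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `mirmod_run`: `mrna` and `mirna` stage
#'   results (sweeps, chosen route), `modules` (a `mirmod_modules`), and
#'   `counts` (entity bookkeeping per stage).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  map <- load_input(cfg$map, "map", "map")
  mrna_expr <- load_input(cfg$mrna_expr, "expression", "mrna_expr")
  mirna_expr <- load_input(cfg$mirna_expr, "expression", "mirna_expr")

  n_in <- c(mrna = nrow(map), mirna = ncol(map))
  al_r <- align_entities(map, mrna_expr, "rows")
  al_c <- align_entities(al_r$map, mirna_expr, "cols")
  map <- al_c$map
  mrna_expr <- al_r$expr
  mrna_expr <- expression_matrix(unclass(mrna_expr)[rownames(map), , drop = FALSE])
  mirna_expr <- al_c$expr
  message(sprintf("[align] %d/%d mRNAs and %d/%d miRNAs retained",
                  nrow(map), n_in[["mrna"]], ncol(map), n_in[["mirna"]]))

  seeds <- derive_seeds(cfg$seed, 4L)
  num_cov_m <- cfg$num_cov %||% max(1L, round(sqrt(ncol(map))))
  num_cov_i <- cfg$num_cov %||% max(1L, round(sqrt(nrow(map))))
  tmap <- transpose_map(map)

  mrna_side <- sweep_side(
    cfg$mrna_method,
    d_un = unguided_dissimilarity(map, "rows"),
    d_gd = function() guided_dissimilarity(
      forest_proximity(map, mrna_expr, n_trees = cfg$n_trees,
                       node_size = cfg$node_size, num_cov = num_cov_m,
                       seed = seeds[1L], row_bootstrap = cfg$row_bootstrap)),
    map_profiles = map, K_grid = cfg$K_mrna, cfg = cfg,
    keep_singletons = FALSE, seed = seeds[2L], side = "mRNA")

  mirna_side <- sweep_side(
    cfg$mirna_method,
    d_un = unguided_dissimilarity(map, "cols"),
    d_gd = function() guided_dissimilarity(
      forest_proximity(tmap, mirna_expr, n_trees = cfg$n_trees,
                       node_size = cfg$node_size, num_cov = num_cov_i,
                       seed = seeds[3L], row_bootstrap = cfg$row_bootstrap)),
    map_profiles = tmap, K_grid = cfg$K_mirna, cfg = cfg,
    keep_singletons = TRUE, seed = seeds[4L], side = "miRNA")

  r_gene <- retained_clusters(mrna_side$sweep)
  r_mir <- retained_clusters(mirna_side$sweep)
  message(sprintf("[enrich] %d mRNA and %d miRNA clusters retained for step 2",
                  length(r_gene), length(r_mir)))
  if (length(r_gene) == 0L || length(r_mir) == 0L) {
    abort("no retained clusters on one side; nothing to pair in step 2")
  }

  modules <- identify_modules(
    r_mir, r_gene, map, mirna_expr, mrna_expr,
    direction = cfg$direction, alpha_level = cfg$alpha_level,
    alpha = cfg$alpha, majority_threshold = cfg$majority_threshold,
    B = cfg$B, seed = derive_seeds(cfg$seed + 1L, 1L))
  message(sprintf("[modules] %d candidates -> %d regulatory",
                  nrow(modules$modules), sum(modules$modules$regulatory)))

  run <- structure(
    list(mrna = mrna_side, mirna = mirna_side, modules = modules,
         map = map, config = cfg,
         counts = tibble::tibble(
           stage = c("input_mrna", "input_mirna", "aligned_mrna",
                     "aligned_mirna", "retained_mrna_clusters",
                     "retained_mirna_clusters", "candidate_modules",
                     "regulatory_modules"),
           n = c(n_in[["mrna"]], n_in[["mirna"]], nrow(map), ncol(map),
                 length(r_gene), length(r_mir), nrow(modules$modules),
                 sum(modules$modules$regulatory)))),
    class = "mirmod_run"
  )
  if (!is.null(cfg$out_dir)) write_run(run, cfg$out_dir)
  run
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- run$config
  for (side in c("mrna", "mirna")) {
    s <- run[[side]]$sweep
    write_tsv(tidy(s$clusters)[c("id", "cluster")],
              file.path(dir, paste0(side, "_clusters.tsv")))
    jsonlite::write_json(
      list(K = s$selected_K, method = s$method, algorithm = s$algorithm,
           medoids = s$clusters$medoid_ids, seed = cfg$seed),
      file.path(dir, paste0(side, "_clusters.json")),
      auto_unbox = TRUE, digits = NA)
    write_tsv(s$table, file.path(dir, paste0(side, "_sweep.tsv")))
    jsonlite::write_json(s$evaluation$results,
                         file.path(dir, paste0(side, "_enrichment.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  mods <- run$modules$modules
  jsonlite::write_json(
    purrr::pmap(mods, function(...) {
      r <- list(...)
      r$targeting_fraction <- as.list(setNames(r$targeting_fraction,
                                               r$mirna_ids))
      r
    }),
    file.path(dir, "modules.json"), auto_unbox = TRUE, digits = NA)
  write_tsv(module_edges(run$modules), file.path(dir, "module_edges.tsv"))
  # inputs and destination are machine-local; echo only the analysis knobs
  cfg_echo <- cfg[setdiff(names(cfg),
                          c("map", "mirna_expr", "mrna_expr", "out_dir"))]
  cfg_echo <- purrr::map(cfg_echo, function(x) if (is.null(x)) NA else x)
  jsonlite::write_json(
    list(package = "mirmod",
         version = as.character(utils::packageVersion("mirmod")),
         seed = cfg$seed, config = cfg_echo, counts = run$counts),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.mirmod_run <- function(x, ...) {
  cat("two-step miRmR module identification run\n")
  print(x$counts, n = Inf)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mirmod_run <- function(x, ...) tidy(x$modules)

#' @exportS3Method generics::glance
glance.mirmod_run <- function(x, ...) glance(x$modules)
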