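config_error <- function(...) {
  stop(structure(class = c("bdgcoex_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

data_error <- function(...) {
  stop(structure(class = c("bdgcoex_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

.required_config <- c("annotation", "matrix", "query", "out_dir", "seed")

.load_config <- function(config) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) config_error("config file not found: ", config)
    yaml::read_yaml(config)
  } else config
  missing <- setdiff(.required_config, names(cfg))
  if (length(missing))
    config_error("config missing field(s): ", paste(missing, collapse = ", "))
  if (length(cfg$query) != 2L)
    config_error("query must name exactly two genes (minus, plus)")
  defaults <- list(matrix_format = "auto", max_distance = 1000,
                   min_cells_per_gene = 3, min_genes_per_cell = 1,
                   impute_threshold = 0.5, k_neighbors = 20,
                   max_iter = 100, correlation_scale = "counts",
                   absolute = FALSE, write_imputed = FALSE)
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (!cfg$correlation_scale %in% c("counts", "log"))
    config_error("correlation_scale must be 'counts' or 'log'")
  cfg
}

#' Run the bidirectional co-expression pipeline end to end
#'
#' Stages, in order: build the bidirectional-pair catalog from the
#' annotation; read and filter the count matrix; normalize (CP10K/log1p);
#' fit the dropout mixture; impute; correlate every catalog pair on the
#' configured scale; rank the query pair. Each stage writes its output to
#' `out_dir` as it completes, and a run manifest records config, input
#' checksums, seed, and per-stage dimensions, so a partial failure leaves
#' the completed stages on disk. The run is deterministic for a fixed
#' config and seed.
#'
#' @param config Path to a YAML config, or an equivalent named list.
#'   Required fields: `annotation` (GTF or gene-table path), `matrix`
#'   (dense TSV path or 10x triplet directory), `query` (two gene ids,
#'   minus then plus), `out_dir`, `seed`. Optional: `matrix_format`,
#'   `max_distance` (default 1000), `min_cells_per_gene` (3),
#'   `min_genes_per_cell` (1), `impute_threshold` (0.5), `k_neighbors`
#'   (20), `max_iter` (100), `correlation_scale` (`"counts"`, the scale the
#'   headline percentile is computed on, or `"log"`), `absolute` (rank on
#'   `|r|`), `write_imputed` (write the imputed matrix, default off).
#' @return Invisibly, a list with `catalog`, `correlations`,
#'   `distribution`, `manifest`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- .load_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  manifest <- list(
    tool = paste0("bdgcoex ", as.character(utils::packageVersion("bdgcoex"))),
    config = cfg[setdiff(names(cfg), "out_dir")],
    seed = cfg$seed,
    inputs = list(),
    stages = list(),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z")
  )
  for (f in c(cfg$annotation, cfg$matrix))
    if (file.exists(f) && !dir.exists(f))
      manifest$inputs[[f]] <- unname(tools::md5sum(f))
  .stage_done <- function(name, ...) {
    manifest$stages[[name]] <<- list(..., at = format(Sys.time(), "%H:%M:%S"))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  if (!file.exists(cfg$annotation)) data_error("annotation not found: ", cfg$annotation)
  genes <- read_gene_models(cfg$annotation)
  catalog <- detect_bdg_pairs(genes, max_distance = cfg$max_distance)
  if (nrow(catalog) == 0L) data_error("no bidirectional pairs detected")
  write_bdg_catalog(catalog, file.path(cfg$out_dir, "bdg_catalog.tsv"))
  .stage_done("catalog", n_genes = nrow(genes), n_pairs = nrow(catalog))

  in_catalog <- (catalog$minus_gene == cfg$query[1L] & catalog$plus_gene == cfg$query[2L]) |
                (catalog$minus_gene == cfg$query[2L] & catalog$plus_gene == cfg$query[1L])
  if (!any(in_catalog))
    data_error("query pair ", paste(cfg$query, collapse = "/"),
               " is not in the detected catalog")

  mat <- tryCatch(read_matrix(cfg$matrix, format = cfg$matrix_format),
                  error = function(e) data_error("reading matrix: ", conditionMessage(e)))
  mat <- filter_matrix(mat, cfg$min_cells_per_gene, cfg$min_genes_per_cell)
  .stage_done("ingest", n_genes = nrow(mat$values), n_cells = ncol(mat$values))

  norm <- normalize_cp10k_log(mat)
  set.seed(cfg$seed)
  model <- fit_dropout_model(norm, max_iter = cfg$max_iter, seed = cfg$seed)
  write_dropout_model(model, file.path(cfg$out_dir, "dropout_model.tsv"))
  imputed <- impute_matrix(norm, model, threshold = cfg$impute_threshold,
                           k_neighbors = min(cfg$k_neighbors, ncol(norm$values) - 1L))
  if (isTRUE(cfg$write_imputed))
    write_matrix(imputed, file.path(cfg$out_dir, "imputed_matrix.tsv"))
  .stage_done("impute",
              n_dropout_entries = sum(model$dropout_prob > cfg$impute_threshold))

  work <- if (cfg$correlation_scale == "counts") denormalize_cp10k_log(imputed) else imputed
  cors <- pair_correlations(work, catalog)
  fwrite(as.data.table(cors), file.path(cfg$out_dir, "pair_correlations.tsv"),
         sep = "\t")
  .stage_done("correlate", n_scored = sum(cors$status == "ok"))

  dist <- tryCatch(
    correlation_distribution(cors, query = cfg$query, absolute = cfg$absolute),
    error = function(e) data_error(conditionMessage(e)))
  fwrite(distribution_histogram(dist),
         file.path(cfg$out_dir, "correlation_histogram.tsv"), sep = "\t")
  jsonlite::write_json(
    list(query = dist$query, query_r = dist$query_r,
         query_percentile = dist$query_percentile, n_pairs = dist$n_pairs,
         scale = cfg$correlation_scale,
         absolute = cfg$absolute),
    file.path(cfg$out_dir, "percentile_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .stage_done("rank", query_percentile = dist$query_percentile)

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(catalog = catalog, correlations = cors, distribution = dist,
                 manifest = manifest, out_dir = cfg$out_dir))
}
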