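#' Read an expression matrix
#'
#' Accepts either a dense TSV (genes in columns, header = gene symbols,
#' first column = cell ids) or a MatrixMarket triple
#' \code{<prefix>.mtx} / \code{<prefix>_barcodes.tsv} /
#' \code{<prefix>_features.tsv} (cells x genes orientation is inferred from
#' the side matching the barcode count).
#'
#' @param path TSV file path, or the \code{.mtx} path of a MatrixMarket
#'   triple.
#' @return Dense numeric matrix, cells x genes, dimnames set.
#' @export
read_expression <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- Matrix::readMM(path)
    prefix <- sub("\\.mtx$", "", path)
    bc <- readLines(paste0(prefix, "_barcodes.tsv"))
    ft <- readLines(paste0(prefix, "_features.tsv"))
    if (nrow(m) == length(ft) && ncol(m) == length(bc)) m <- Matrix::t(m)
    if (nrow(m) != length(bc) || ncol(m) != length(ft))
      stop("read_expression: matrix dimensions match neither barcodes x features nor its transpose")
    m <- as.matrix(m)
    dimnames(m) <- list(bc, ft)
    return(m)
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                          check.names = FALSE)
  as.matrix(df)
}

#' Write an expression matrix as dense TSV
#' @param expr Cells x genes matrix.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(cell_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-cell cluster labels (two-column TSV: cell_id, cluster)
#' @param path TSV path.
#' @return Named character vector of cluster labels.
#' @export
read_clusters <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[2]]), df[[1]])
}

#' Assemble a run configuration
#'
#' Parameters default to the package-wide desk-scale settings; \code{mode =
#' "paper"} raises the sampling-intensive settings (bootstrap replicates and
#' posterior draws to 10000) to the high-fidelity values. Unknown keys in
#' \code{...} or the YAML file are rejected.
#'
#' @param config_file Optional YAML file with the same keys.
#' @param ... Key-value overrides (applied after the file).
#' @return A \code{run_config} list.
#' @export
run_config <- function(config_file = NULL, ...) {
  cfg <- list(
    reads = NULL, expression = NULL, panel = NULL, clusters = NULL,
    complex_db = NULL, out_dir = "spatmap_out",
    width_px = 2048L, height_px = 2048L, tile = 16L, n_cells = 1800L,
    n_neighbors = 15L, t_diffusion = 3L, k_min = 2L, k_max = 8L,
    lam = 0.9, sigma = 1, blur = 2, reach = 10, n_boot = 1000L,
    k_elbow = 20L, n_samples = 2000L, marking_gene = NULL,
    seed = 1L, mode = "desk")
  apply_over <- function(cfg, over, origin) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("run_config: unknown key(s) in ", origin, ": ",
           paste(unknown, collapse = ", "))
    utils::modifyList(cfg, over)
  }
  if (!is.null(config_file))
    cfg <- apply_over(cfg, yaml::read_yaml(config_file), config_file)
  cfg <- apply_over(cfg, list(...), "overrides")
  if (!cfg$mode %in% c("desk", "paper"))
    stop("run_config: mode must be 'desk' or 'paper'")
  if (cfg$mode == "paper") {
    cfg$n_boot <- 10000L
    cfg$n_samples <- 10000L
  }
  structure(cfg, class = "run_config")
}

#' Run pipeline stages
#'
#' Executes the requested stages in dependency order on the inputs named in
#' the configuration, writing each stage's artifacts plus a JSON manifest
#' (input checksums, parameters, seed, package version) into
#' \code{out_dir}. A stage whose manifest is up to date is skipped unless
#' \code{force = TRUE}.
#'
#' Stages: \code{simulate} (synthetic tissue standing in for reads +
#' expression), \code{bin-reads}, \code{fit-model}, \code{map},
#' \code{evaluate}, \code{marking}, \code{ccc}.
#'
#' @param cfg A [run_config()].
#' @param stages Character vector of stage names (default: the core mapping
#'   chain).
#' @param force Re-run stages even when up to date.
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(cfg, stages = c("bin-reads", "fit-model", "map"),
                         force = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  all_stages <- c("simulate", "bin-reads", "fit-model", "map", "evaluate",
                  "marking", "ccc")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("run_pipeline: unknown stage(s): ",
                        paste(bad, collapse = ", "))
  stages <- all_stages[all_stages %in% stages]
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  state <- new.env()

  manifest_path <- function(stage) file.path(cfg$out_dir,
                                             paste0(stage, ".manifest.json"))
  stage_manifest <- function(stage, inputs) {
    files <- inputs[!vapply(inputs, is.null, logical(1))]
    sums <- if (length(files)) as.list(tools::md5sum(unlist(files))) else list()
    list(stage = stage, inputs = sums,
         parameters = unclass(cfg)[!names(cfg) %in%
                                     c("reads", "expression", "panel",
                                       "clusters", "complex_db", "out_dir")],
         version = as.character(utils::packageVersion("spatmap")))
  }
  up_to_date <- function(stage, inputs) {
    mp <- manifest_path(stage)
    file.exists(mp) &&
      identical(jsonlite::fromJSON(mp, simplifyVector = TRUE),
                jsonlite::fromJSON(jsonlite::toJSON(
                  stage_manifest(stage, inputs), auto_unbox = TRUE),
                  simplifyVector = TRUE))
  }
  finish <- function(stage, inputs) {
    jsonlite::write_json(stage_manifest(stage, inputs), manifest_path(stage),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  log_stage <- function(stage, msg = "running") {
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
  }

  reads_path <- cfg$reads
  expr_path <- cfg$expression
  panel_path <- cfg$panel

  if ("simulate" %in% stages) {
    inputs <- list()
    reads_path <- file.path(cfg$out_dir, "reads.tsv")
    expr_path <- file.path(cfg$out_dir, "expression.tsv")
    panel_path <- file.path(cfg$out_dir, "panel.txt")
    if (!force && up_to_date("simulate", inputs) &&
        all(file.exists(reads_path, expr_path, panel_path))) {
      log_stage("simulate", "up to date, skipped")
    } else {
      log_stage("simulate")
      tis <- simulate_tissue(tissue_spec(width_px = cfg$width_px,
                                         height_px = cfg$height_px,
                                         tile = cfg$tile,
                                         n_cells = cfg$n_cells,
                                         seed = cfg$seed))
      utils::write.table(tis$reads, reads_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      write_expression(tis$expr, expr_path)
      writeLines(tis$panel, panel_path)
      res$simulate <- tis
      finish("simulate", inputs)
    }
  }
  need <- function(path, what, stage) {
    if (is.null(path) || !file.exists(path))
      stop(sprintf("run_pipeline: stage '%s' needs %s; run the prerequisite stage or set the config path",
                   stage, what))
    path
  }

  if (any(c("bin-reads", "fit-model", "map", "evaluate", "marking", "ccc")
          %in% stages)) {
    grid <- grid_spec(cfg$width_px, cfg$height_px, cfg$tile)
    state$sg <- NULL
  }
  if (any(c("bin-reads", "map", "evaluate", "ccc") %in% stages)) {
    rp <- need(reads_path, "a spot table (reads)", "bin-reads")
    pp <- need(panel_path, "a landmark panel", "bin-reads")
    log_stage("bin-reads")
    state$sg <- aggregate_reads(read_spot_table(rp), grid, read_panel(pp))
    if ("bin-reads" %in% stages) {
      write_signature_grid(state$sg, file.path(cfg$out_dir, "signatures.tsv"))
      finish("bin-reads", list(reads = rp, panel = pp))
      res$`bin-reads` <- state$sg
    }
  }
  if (any(c("fit-model", "map", "evaluate", "marking", "ccc") %in% stages)) {
    ep <- need(expr_path, "an expression matrix", "fit-model")
    log_stage("impute")
    expr <- read_expression(ep)
    state$imputed <- impute_expression(expr, cfg$n_neighbors, cfg$t_diffusion)
  }
  if (any(c("fit-model", "map", "evaluate", "ccc") %in% stages)) {
    log_stage("fit-model")
    state$models <- fit_all_landmarks(state$imputed, state$sg$panel,
                                      k_range = cfg$k_min:cfg$k_max,
                                      seed = cfg$seed)
    if ("fit-model" %in% stages) {
      write_on_off_models(state$models,
                          file.path(cfg$out_dir, "onoff_models.tsv"))
      finish("fit-model", list(expression = expr_path))
      res$`fit-model` <- state$models
    }
  }
  if (any(c("map", "ccc") %in% stages)) {
    log_stage("map")
    state$mm <- map_cells(state$imputed, state$sg, models = state$models,
                          lam = cfg$lam)
    if ("map" %in% stages) {
      write_mapping(state$mm, file.path(cfg$out_dir, "mapping"))
      finish("map", list(reads = reads_path, expression = expr_path))
      res$map <- state$mm
    }
  }
  if ("evaluate" %in% stages) {
    log_stage("evaluate")
    rep <- evaluate_reconstruction(state$sg, state$imputed, lam = cfg$lam,
                                   blur = cfg$blur, n_boot = cfg$n_boot,
                                   seed = cfg$seed, models = state$models)
    utils::write.table(rep, file.path(cfg$out_dir, "evaluation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    finish("evaluate", list(reads = reads_path, expression = expr_path))
    res$evaluate <- rep
  }
  if ("marking" %in% stages) {
    cp <- need(cfg$clusters, "a cluster-label TSV", "marking")
    if (is.null(cfg$marking_gene))
      stop("run_pipeline: stage 'marking' needs config key 'marking_gene'")
    log_stage("marking")
    cl <- read_clusters(cp)
    x <- state$imputed[, cfg$marking_gene]
    model <- fit_marking_model(x, cl[rownames(state$imputed)],
                               n_samples = cfg$n_samples, seed = cfg$seed)
    summ <- summarize_marking(model)
    utils::write.table(summ, file.path(cfg$out_dir, "marking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    finish("marking", list(expression = expr_path, clusters = cp))
    res$marking <- summ
  }
  if ("ccc" %in% stages) {
    dp <- need(cfg$complex_db, "a ligand-receptor complex table", "ccc")
    log_stage("ccc")
    rk <- rank_interactions(read_complex_table(dp), state$imputed, state$mm,
                            reach = cfg$reach, blur = cfg$blur)
    utils::write.table(rk, file.path(cfg$out_dir, "ccc_ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    finish("ccc", list(expression = expr_path, complex_db = dp))
    res$ccc <- rk
  }
  invisible(res)
}
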