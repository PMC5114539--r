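# File I/O and configuration glue.

#' Read an item pool from CSV or JSON
#'
#' The pool schema is: `id`, loading columns `a_1..a_P`, `b` (difficulty),
#' optional `c` (pseudo-guessing, default 0), `testlet_id`. The format is
#' chosen from the file extension. Validation is strict: missing columns,
#' non-finite values, out-of-range guessing parameters, empty testlets or
#' duplicated item ids raise errors naming the offending field.
#'
#' @param path file path (`.csv` or `.json`).
#' @return validated item-pool data frame with attribute `P`.
#' @export
read_item_pool <- function(path) {
  if (!file.exists(path)) stop("pool file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pool <- switch(ext,
    csv = utils::read.csv(path, stringsAsFactors = FALSE),
    json = as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE),
    stop("unsupported pool format '.", ext, "' (use .csv or .json)"))
  validate_item_pool(pool)
}

#' Validate an item-pool data frame
#'
#' @param pool data frame to validate (see [read_item_pool()] for the schema).
#' @return the pool, with `c` filled in if absent and attribute `P` set.
#' @export
validate_item_pool <- function(pool) {
  acols <- grep("^a_[0-9]+$", names(pool), value = TRUE)
  P <- length(acols)
  if (P == 0L) stop("pool schema: no loading columns a_1..a_P found")
  if (!setequal(acols, paste0("a_", seq_len(P)))) {
    stop("pool schema: loading columns must be consecutively numbered a_1..a_P")
  }
  for (col in c("id", "b", "testlet_id")) {
    if (!col %in% names(pool)) stop("pool schema: missing column '", col, "'")
  }
  if (anyDuplicated(pool$id)) stop("pool schema: duplicated item ids")
  if (!"c" %in% names(pool)) pool$c <- 0
  num <- c(paste0("a_", seq_len(P)), "b", "c")
  for (col in num) {
    v <- pool[[col]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      stop("pool schema: column '", col, "' must be finite numeric")
    }
  }
  if (any(pool$c < 0 | pool$c >= 1)) stop("pool schema: 'c' must lie in [0, 1)")
  if (any(rowSums(abs(as.matrix(pool[paste0("a_", seq_len(P))]))) == 0)) {
    warning("pool contains item(s) with all-zero loadings")
  }
  if (any(is.na(pool$testlet_id) | pool$testlet_id == "")) {
    stop("pool schema: every item needs a non-empty testlet_id")
  }
  attr(pool, "P") <- P
  pool
}

#' Write an item pool to CSV
#'
#' @param pool item-pool data frame.
#' @param path output path.
#' @export
write_item_pool <- function(pool, path) {
  utils::write.csv(pool, path, row.names = FALSE)
  invisible(path)
}

.config_defaults <- function() {
  list(seed = 1L, N = 500L, replications = 2L, max_items = 54L,
       P = 3L, rho = 0.80, info_mode = "sum",
       shrinkage = "calibrate", shrinkage_N = 5000L,
       burn_min = 1000L, burn_cap = 5000L, check_every = 500L,
       retain = 500L,
       conditions = list(list(size = 3L, sigma2 = 0, model = "MTIRT",
                              algorithm = "MAT")))
}

#' Load and validate a study configuration
#'
#' Reads a YAML configuration, fills defaults for every omitted key and
#' rejects unknown keys. `conditions` is a list of cells with fields `size`,
#' `sigma2`, `model` (MTIRT/MIRT) and `algorithm` (MAT/RAN).
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defaults <- .config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, raw[setdiff(names(raw), "conditions")])
  if (!is.null(raw$conditions)) cfg$conditions <- raw$conditions
  stopifnot_msg <- function(ok, msg) if (!ok) stop("config: ", msg)
  stopifnot_msg(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed),
                "'seed' must be an integer")
  stopifnot_msg(cfg$N >= 1, "'N' must be at least 1")
  stopifnot_msg(cfg$replications >= 1, "'replications' must be at least 1")
  stopifnot_msg(cfg$rho > -1 && cfg$rho < 1, "'rho' must lie in (-1, 1)")
  stopifnot_msg(cfg$info_mode %in% c("sum", "mean"), "'info_mode' must be sum or mean")
  stopifnot_msg(cfg$shrinkage %in% c("calibrate", "closed_form"),
                "'shrinkage' must be calibrate or closed_form")
  for (cd in cfg$conditions) {
    miss <- setdiff(c("size", "sigma2", "model", "algorithm"), names(cd))
    stopifnot_msg(length(miss) == 0,
                  paste0("condition missing field(s): ", paste(miss, collapse = ", ")))
    stopifnot_msg(cd$sigma2 >= 0, "condition 'sigma2' must be non-negative")
    stopifnot_msg(cd$model %in% c("MTIRT", "MIRT"), "condition 'model' must be MTIRT or MIRT")
    stopifnot_msg(cd$algorithm %in% c("MAT", "RAN"), "condition 'algorithm' must be MAT or RAN")
    stopifnot_msg(cfg$max_items %% cd$size == 0,
                  "'max_items' must be a multiple of every condition's testlet size")
  }
  cfg
}

#' Condition grid from a configuration
#'
#' @param cfg configuration from [load_config()].
#' @return data frame with one row per condition.
#' @export
config_conditions <- function(cfg) {
  do.call(rbind, lapply(cfg$conditions, function(cd) {
    data.frame(size = as.integer(cd$size), sigma2 = as.numeric(cd$sigma2),
               model = cd$model, algorithm = cd$algorithm,
               stringsAsFactors = FALSE)
  }))
}

#' Write study results with a reproducibility manifest
#'
#' Writes `condition_results.csv`, `replications.csv` and (when present)
#' `shrinkage_table.csv` with fixed column order and three-decimal formatting
#' of the summary columns, plus `manifest.json` recording the seed, the
#' normalized configuration, its MD5 hash and the package version, so a run
#' is reconstructible from its manifest.
#'
#' @param study result of [run_study()].
#' @param out_dir output directory (created if needed).
#' @param cfg configuration used (stored in the manifest).
#' @param seed root seed used.
#' @return invisibly, the paths written.
#' @export
write_results <- function(study, out_dir, cfg = NULL, seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(df, cols) {
    for (col in intersect(cols, names(df))) df[[col]] <- sprintf("%.3f", df[[col]])
    df
  }
  res_cols <- c("size", "sigma2", "model", "algorithm", "mse", "mse_se",
                "var_hat", "var_hat_se", "n_reps")
  res <- study$results
  if (is.null(res)) {
    res <- data.frame(matrix(nrow = 0, ncol = length(res_cols),
                             dimnames = list(NULL, res_cols)))
  }
  paths <- file.path(out_dir, c("condition_results.csv", "replications.csv",
                                "shrinkage_table.csv", "manifest.json"))
  utils::write.csv(fmt(res[res_cols[res_cols %in% names(res)]],
                       c("mse", "mse_se", "var_hat", "var_hat_se")),
                   paths[1], row.names = FALSE)
  reps <- study$replications
  if (is.null(reps)) reps <- data.frame()
  utils::write.csv(reps, paths[2], row.names = FALSE)
  if (!is.null(study$shrinkage)) {
    utils::write.csv(fmt(study$shrinkage, "factor"), paths[3], row.names = FALSE)
  }
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, null = "null")
  tmp <- tempfile(fileext = ".json")
  writeLines(cfg_json, tmp)
  manifest <- list(seed = seed,
                   config = if (is.null(cfg)) NULL else cfg,
                   config_md5 = unname(tools::md5sum(tmp)),
                   package_version = as.character(utils::packageVersion("testletMAT")),
                   written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  unlink(tmp)
  jsonlite::write_json(manifest, paths[4], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}
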