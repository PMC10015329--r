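#' Save and reload a sweep as plain-text files
#'
#' `write_sweep()` writes a sweep to a directory: `summary.csv` (one row
#' per parameter value), `config.json` (sweep configuration, model
#' parameters and classification threshold), `network.edgelist`, and one
#' `samples/block_<k>.csv` per parameter value (first row: the state at
#' the end of relaxation; remaining `M` rows: the samples).
#' `read_sweep()` reconstructs the `dw_sweep` from such a directory.
#'
#' @param sweep a [run_sweep()] result.
#' @param dir directory path (created if needed).
#' @return `write_sweep()` returns `dir` invisibly; `read_sweep()` returns
#'   a `dw_sweep`.
#' @export
write_sweep <- function(sweep, dir) {
  stopifnot(inherits(sweep, "dw_sweep"))
  dir.create(file.path(dir, "samples"), recursive = TRUE,
             showWarnings = FALSE)
  utils::write.csv(sweep$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  write_network(sweep$net, file.path(dir, "network.edgelist"))
  jsonlite::write_json(
    list(config = unclass(sweep$config), params = unclass(sweep$params),
         threshold = sweep$threshold, initial_side = sweep$initial_side),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  for (k in seq_along(sweep$blocks)) {
    b <- sweep$blocks[[k]]
    m <- rbind(b$state_at_relax, b$samples)
    colnames(m) <- paste0("node_", seq_len(ncol(m)))
    utils::write.csv(as.data.frame(m),
                     file.path(dir, "samples",
                               sprintf("block_%04d.csv", k)),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_sweep
#' @export
read_sweep <- function(dir) {
  cfg_path <- file.path(dir, "config.json")
  if (!file.exists(cfg_path))
    stop("not a sweep directory (missing config.json): ", dir,
         call. = FALSE)
  meta <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  config <- structure(meta$config, class = "dw_sweep_config")
  params <- structure(meta$params, class = "dw_params")
  net <- read_network(file.path(dir, "network.edgelist"))
  summary <- tibble::as_tibble(
    utils::read.csv(file.path(dir, "summary.csv")))
  files <- sort(list.files(file.path(dir, "samples"),
                           pattern = "^block_\\d+\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0L)
    stop("sweep directory has no sample blocks: ", dir, call. = FALSE)
  blocks <- purrr::map2(files, seq_along(files), function(f, k) {
    m <- as.matrix(utils::read.csv(f))
    dimnames(m) <- NULL
    samples <- m[-1L, , drop = FALSE]
    structure(
      list(param_value = summary$param_value[k],
           sample_times = config$relax_time +
             config$sample_interval * seq_len(nrow(samples)),
           samples = samples, state_at_relax = m[1L, ],
           means = colMeans(samples),
           sds = apply(samples, 2L, stats::sd),
           labels = classify_states(colMeans(samples), meta$threshold)),
      class = "dw_block")
  })
  structure(list(summary = summary, blocks = blocks,
                 threshold = meta$threshold,
                 initial_side = meta$initial_side, config = config,
                 params = params, net = net),
            class = "dw_sweep")
}
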