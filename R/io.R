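#' Default configuration
#'
#' Full default configuration of the simulator as a nested list, with one
#' block per module.  All values are overridable from a YAML file via
#' [load_config()].
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    kernel = list(dt = 1e-4, coarse_dt = 1.2, delay = 8e-4, seed = 1),
    neurons = unclass(neuron_params()),
    stp = list(U = 0.2, tau_f = 0.6, tau_d = 0.1, enabled = TRUE),
    plasticity_exc = unclass(exc_plasticity_params()),
    consolidation = list(P = 20, w_P = 0.5, tau_cons = 1200,
                         interval = 1.2, enabled = TRUE),
    plasticity_inh = unclass(inh_plasticity_params()),
    network = list(n_exc = 1024, n_inh = 256, p_rec = 0.1,
                   grid = c(64, 64), radius = 8,
                   weights = list(input_e = 0.2, e_e = 0.1, e_i = 0.1,
                                  i_e = 0.3, i_i = 0.3)),
    stimulation = list(background_rate = 10, stim_increment = 35,
                       T_on = 1, T_off = 2, burn_in = 50)
  )
}

.validate_config <- function(cfg) {
  chk <- function(ok, key, what) {
    if (!ok) stop("invalid config value for '", key, "': ", what,
                  call. = FALSE)
  }
  chk(cfg$kernel$dt > 0, "kernel.dt", "must be > 0")
  r <- cfg$kernel$coarse_dt / cfg$kernel$dt
  chk(abs(r - round(r)) < 1e-6, "kernel.coarse_dt",
      "must be an integer multiple of dt")
  chk(cfg$kernel$delay >= 0, "kernel.delay", "must be >= 0")
  chk(cfg$stp$U >= 0 && cfg$stp$U <= 1, "stp.U", "must lie in [0, 1]")
  chk(cfg$stp$tau_f > 0 && cfg$stp$tau_d > 0, "stp.tau_f/tau_d",
      "must be > 0")
  chk(cfg$plasticity_exc$w_max > 0, "plasticity_exc.w_max", "must be > 0")
  chk(all(c(cfg$plasticity_exc$tau_plus, cfg$plasticity_exc$tau_minus,
            cfg$plasticity_exc$tau_slow) > 0),
      "plasticity_exc.tau_*", "must be > 0")
  chk(cfg$consolidation$P > 0, "consolidation.P", "must be > 0")
  chk(cfg$plasticity_inh$eta >= 0, "plasticity_inh.eta", "must be >= 0")
  chk(cfg$network$p_rec >= 0 && cfg$network$p_rec <= 1, "network.p_rec",
      "must lie in [0, 1]")
  chk(cfg$stimulation$background_rate >= 0, "stimulation.background_rate",
      "must be >= 0")
  invisible(cfg)
}

#' Load and validate a configuration file
#'
#' Reads a YAML configuration, rejects unknown keys, fills missing values
#' with the defaults and validates all parameters against their
#' constraints.  An empty file yields the full default configuration.
#'
#' @param path path to a YAML file.
#' @return the validated, completed configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  def <- default_config()
  bad <- setdiff(names(user), names(def))
  if (length(bad)) stop("unknown config block(s): ",
                        paste(bad, collapse = ", "))
  for (blk in names(user)) {
    bad <- setdiff(names(user[[blk]]), names(def[[blk]]))
    if (length(bad)) stop("unknown key(s) in block '", blk, "': ",
                          paste(bad, collapse = ", "))
  }
  cfg <- utils::modifyList(def, user)
  .validate_config(cfg)
  cfg
}

#' Write a protocol result to a directory
#'
#' Serialises a protocol result: spike rasters as two-column TSV
#' (`time_s`, `neuron_id`, 0-based ids), weight matrices in Matrix Market
#' coordinate format (1-based indices, per the MTX standard -- note the
#' dialect difference from the 0-based raster ids) with a JSON sidecar
#' (dimensions, class label), the summary as JSON, and a manifest with the
#' seed, config snapshot and MD5 checksums of every file.
#'
#' @param result a protocol result (list with elements `protocol`, `seed`,
#'   `config`, optional named lists `rasters` and `weights`, and `summary`).
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
write_protocol_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(result$rasters)) {
    f <- file.path(dir, paste0("raster_", nm, ".tsv"))
    utils::write.table(result$rasters[[nm]], f, sep = "\t",
                       row.names = FALSE, col.names = c("time_s", "neuron_id"),
                       quote = FALSE)
    files <- c(files, f)
  }
  for (nm in names(result$weights)) {
    wt <- result$weights[[nm]]
    f <- file.path(dir, paste0("weights_", nm, ".mtx"))
    m <- Matrix::sparseMatrix(i = wt$pre + 1L, j = wt$post + 1L, x = wt$w,
                              dims = c(wt$n_pre, wt$n_post))
    Matrix::writeMM(m, f)
    side <- list(n_pre = wt$n_pre, n_post = wt$n_post,
                 class = wt$class, indexing = "1-based (MTX standard)")
    fs <- file.path(dir, paste0("weights_", nm, ".json"))
    jsonlite::write_json(side, fs, auto_unbox = TRUE)
    files <- c(files, f, fs)
    if (!is.null(wt$wtilde)) {
      f2 <- file.path(dir, paste0("wtilde_", nm, ".mtx"))
      m2 <- Matrix::sparseMatrix(i = wt$pre + 1L, j = wt$post + 1L,
                                 x = wt$wtilde,
                                 dims = c(wt$n_pre, wt$n_post))
      Matrix::writeMM(m2, f2)
      files <- c(files, f2)
    }
  }
  f <- file.path(dir, "summary.json")
  jsonlite::write_json(result$summary, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  manifest <- list(protocol = result$protocol, seed = result$seed,
                   config = result$config,
                   files = lapply(files, function(f)
                     list(name = basename(f),
                          md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read back a protocol result directory
#'
#' Verifies the manifest checksums (error on tampering or partial writes)
#' and loads rasters, weight matrices and the summary.
#'
#' @param dir directory written by [write_protocol_result()].
#' @return list with `manifest`, `rasters`, `weights` (sparse matrices) and
#'   `summary`.
#' @export
read_protocol_result <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = FALSE)
  for (fe in mf$files) {
    f <- file.path(dir, fe$name)
    if (!file.exists(f)) stop("missing file: ", fe$name)
    if (unname(tools::md5sum(f)) != fe$md5)
      stop("checksum mismatch for ", fe$name)
  }
  out <- list(manifest = mf, rasters = list(), weights = list())
  for (fe in mf$files) {
    f <- file.path(dir, fe$name)
    nm <- tools::file_path_sans_ext(fe$name)
    if (startsWith(fe$name, "raster_")) {
      tab <- utils::read.table(f, header = TRUE, sep = "\t")
      names(tab) <- c("time", "id")
      out$rasters[[sub("^raster_", "", nm)]] <- tab
    } else if (startsWith(fe$name, "weights_") &&
               endsWith(fe$name, ".mtx")) {
      out$weights[[sub("^weights_", "", nm)]] <- Matrix::readMM(f)
    }
  }
  out$summary <- jsonlite::read_json(file.path(dir, "summary.json"),
                                     simplifyVector = TRUE)
  out
}
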