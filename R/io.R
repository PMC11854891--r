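# Delimited-text series IO, experiment configuration, the circuit-dataset
# reader and deterministic test-fixture generation. All file formats are
# plain text; no network access ever happens here (external datasets are
# user-supplied by path).

#' Read a multi-node time-series table
#'
#' Delimited text, one column per node and one row per sample; comma, tab or
#' whitespace separated (sniffed from the first line), with an optional
#' header row.
#'
#' @param path file path.
#' @return numeric matrix (rows = samples, columns = nodes).
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else if (grepl("\t", first)) "\t" else ""
  fields <- strsplit(if (sep == "") gsub("[[:space:]]+", " ", trimws(first)) else first,
                     if (sep == "") " " else sep, fixed = sep != "")[[1]]
  header <- anyNA(suppressWarnings(as.numeric(fields)))
  df <- utils::read.table(path, sep = sep, header = header)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric values in series file: ", path, call. = FALSE)
  m
}

#' Write a multi-node time-series table
#'
#' @param x numeric matrix or vector.
#' @param path output file.
#' @param sep field separator (default comma).
#' @param digits significant digits (default 10; fixed formatting keeps
#'   output byte-reproducible).
#' @export
write_series <- function(x, path, sep = ",", digits = 10L) {
  m <- as.matrix(x)
  txt <- apply(m, 1, function(row)
    paste(formatC(row, digits = digits, format = "g"), collapse = sep))
  writeLines(txt, path)
  invisible(path)
}

config_known_keys <- c("family", "topology", "heterogeneity", "integration",
                       "ordinal", "sweep", "seed", "output")

#' Read and validate an experiment configuration
#'
#' YAML file with top-level sections `family`, `topology` (`type`, `n_nodes`,
#' `mean_degree`, `gamma`), `heterogeneity` (`alpha`, `xi`), `integration`
#' (family-specific solver settings, see [run_sweep()] control), `ordinal`
#' (`D`, `tau`, `block_mode`, `poincare`, `threshold`), `sweep` (`d_min`,
#' `d_max`, `n_points`, `direction`, `n_seeds`), `seed` and `output`.
#' Unknown top-level keys are rejected.
#'
#' @param path YAML file.
#' @return object of class `"experiment_config"` (named list), with a
#'   `fingerprint` attribute echoed into all outputs.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), config_known_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  if (is.null(cfg$family) ||
      !cfg$family %in% c("kuramoto", "chialvo", "rossler"))
    stop("config must set family to kuramoto, chialvo or rossler", call. = FALSE)
  if (is.null(cfg$topology$type) || !cfg$topology$type %in% c("star", "scale_free"))
    stop("config must set topology$type to star or scale_free", call. = FALSE)
  if (is.null(cfg$topology$n_nodes))
    stop("config must set topology$n_nodes", call. = FALSE)
  attr(cfg, "fingerprint") <- config_fingerprint(cfg)
  class(cfg) <- "experiment_config"
  cfg
}

# short deterministic fingerprint of a config (md5 of its canonical YAML)
config_fingerprint <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

output_header <- function(cfg = NULL) {
  c(sprintf("# optews %s", as.character(utils::packageVersion("optews"))),
    if (!is.null(cfg)) sprintf("# config %s", attr(cfg, "fingerprint")))
}

#' Read a star-circuit voltage dataset
#'
#' Loads per-coupling voltage recordings of a small star network of
#' oscillator circuits from a directory with the layout
#'
#' ```
#' path/
#'   dataset.yaml          # sampling_rate_hz, transition (continuous|explosive),
#'                         # nodes: [{id, label}], couplings: [{value, file}]
#'   <coupling file>.csv   # one column per node, in the node order of dataset.yaml
#' ```
#'
#' Exactly one node must be labelled `hub` and at least two coupling steps
#' must be present. The published circuit deposit is not distributed with
#' this package; recordings must be arranged into this layout by the user
#' ([fixture_generator()] writes a miniature synthetic example of it).
#'
#' @param path dataset directory.
#' @return object of class `"circuit_dataset"`: list with `voltages` (list of
#'   matrices, one per coupling), `couplings`, `labels`, `sampling_rate_hz`,
#'   `transition`, `source`.
#' @export
load_circuit_dataset <- function(path) {
  expect <- paste("expected layout: <dir>/dataset.yaml (sampling_rate_hz,",
                  "transition, nodes, couplings) plus one CSV per coupling,",
                  "one column per node")
  if (!dir.exists(path))
    stop("dataset directory not found: ", path, "; ", expect, call. = FALSE)
  meta_file <- file.path(path, "dataset.yaml")
  if (!file.exists(meta_file))
    stop("missing dataset.yaml in ", path, "; ", expect, call. = FALSE)
  meta <- yaml::read_yaml(meta_file)
  for (k in c("sampling_rate_hz", "transition", "nodes", "couplings"))
    if (is.null(meta[[k]]))
      stop("dataset.yaml lacks field '", k, "'; ", expect, call. = FALSE)
  labels <- vapply(meta$nodes, `[[`, character(1), "label")
  if (sum(labels == "hub") != 1L)
    stop("dataset must label exactly one node as hub", call. = FALSE)
  if (length(meta$couplings) < 2L)
    stop("dataset must contain at least 2 coupling steps", call. = FALSE)
  couplings <- vapply(meta$couplings, function(cc) as.numeric(cc$value), numeric(1))
  volt <- lapply(meta$couplings, function(cc) {
    f <- file.path(path, cc$file)
    if (!file.exists(f))
      stop("missing coupling file ", cc$file, " referenced by dataset.yaml",
           call. = FALSE)
    m <- read_series(f)
    if (ncol(m) != length(labels))
      stop(sprintf("%s has %d columns but dataset.yaml lists %d nodes",
                   cc$file, ncol(m), length(labels)), call. = FALSE)
    m
  })
  ord <- order(couplings)
  structure(list(voltages = volt[ord], couplings = couplings[ord],
                 labels = labels, sampling_rate_hz = meta$sampling_rate_hz,
                 transition = meta$transition, source = path),
            class = "circuit_dataset")
}

#' @export
print.circuit_dataset <- function(x, ...) {
  cat(sprintf("<circuit_dataset> %d nodes (%d hub), %d coupling steps, %s transition\n",
              length(x$labels), sum(x$labels == "hub"), length(x$couplings),
              x$transition))
  invisible(x)
}

#' Baseline-normalized OPT entropy traces of a circuit dataset
#'
#' For every coupling step and node: Poincare maxima of the voltage,
#' ordinal symbolization, OPT entropy; each node's trace is then normalized
#' to its value at the smallest (uncoupled) coupling step.
#'
#' @param ds a `circuit_dataset`.
#' @param D,tau,block_mode ordinal settings (defaults `3`, `1`, disjoint).
#' @return data.frame with columns `coupling`, `node`, `label`, `HT`,
#'   `HT_norm`.
#' @export
circuit_entropy_traces <- function(ds, D = 3L, tau = 1L, block_mode = "disjoint") {
  stopifnot(inherits(ds, "circuit_dataset"))
  rows <- lapply(seq_along(ds$couplings), function(s) {
    m <- ds$voltages[[s]]
    ht <- vapply(seq_len(ncol(m)), function(i) {
      series_entropies(m[, i], D = D, tau = tau, block_mode = block_mode,
                       poincare = "maxima", warn_short = FALSE)$HT
    }, numeric(1))
    data.frame(coupling = ds$couplings[s], node = seq_len(ncol(m)),
               label = ds$labels, HT = ht)
  })
  out <- do.call(rbind, rows)
  base <- out[out$coupling == min(out$coupling), c("node", "HT")]
  out$HT_norm <- out$HT / base$HT[match(out$node, base$node)]
  out
}

#' Deterministic test fixtures
#'
#' Writes small plain-text datasets with known entropic properties:
#' * `"white-noise"`: 60000 i.i.d. uniform samples (`H` and `HT` near 1),
#' * `"periodic"`: a period-3 sawtooth (`H` and `HT` exactly computable,
#'   `HT = 0`),
#' * `"chialvo-orbit"`: 5000 retained iterations of an isolated Chialvo
#'   neuron at `I = 0.05`,
#' * `"circuit-layout"`: a miniature synthetic circuit-dataset directory
#'   (a short Roessler star run posing as voltage recordings) exercising
#'   [load_circuit_dataset()].
#'
#' Identical `(kind, seed)` produce byte-identical files.
#'
#' @param kind fixture kind (see above).
#' @param seed RNG seed.
#' @param dir output directory (created if needed).
#' @return invisibly, the path(s) written.
#' @export
fixture_generator <- function(kind = c("white-noise", "periodic",
                                       "chialvo-orbit", "circuit-layout"),
                              seed = 1L, dir = tempdir()) {
  kind <- match.arg(kind)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (kind == "white-noise") {
    x <- with_local_seed(seed, runif(60000))
    return(invisible(write_series(x, file.path(dir, "white_noise.csv"))))
  }
  if (kind == "periodic") {
    x <- rep(c(0, 1, 2), length.out = 600)
    return(invisible(write_series(x, file.path(dir, "periodic.csv"))))
  }
  if (kind == "chialvo-orbit") {
    orb <- chialvo_orbit(I = 0.05, n_iters = 5000L, transient_iters = 1000L)
    return(invisible(write_series(orb$x, file.path(dir, "chialvo_orbit.csv"))))
  }
  # circuit-layout: synthetic stand-in for a 6-node star circuit recording
  root <- file.path(dir, "circuit_synthetic")
  if (!dir.exists(root)) dir.create(root)
  net <- build_star(6)
  params <- assign_heterogeneity(net, "rossler", seed = seed)
  couplings <- c(0, 0.002, 0.004)
  files <- sprintf("coupling_%03d.csv", seq_along(couplings))
  for (s in seq_along(couplings)) {
    run <- simulate_rossler(net, params, couplings[s], n_steps = 60000L,
                            transient = 100, store_series = TRUE,
                            series_stride = 4L, seed = seed + s)
    xcols <- run$series[, seq(1, by = 3, length.out = 6)]
    write_series(xcols, file.path(root, files[s]))
  }
  meta <- list(
    name = "synthetic piecewise-Roessler star (simulated stand-in, not the published deposit)",
    sampling_rate_hz = 25,
    transition = "explosive",
    nodes = lapply(seq_len(6), function(i)
      list(id = paste0("node", i), label = if (i == 1) "hub" else "leaf")),
    couplings = lapply(seq_along(couplings), function(s)
      list(value = couplings[s], file = files[s])))
  yaml::write_yaml(meta, file.path(root, "dataset.yaml"))
  invisible(root)
}
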