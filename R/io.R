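# Plain-text, versioned readers and writers for every pipeline artifact.
# All files start with a '# mshbm <kind> v1' header line; readers validate
# it so truncated or foreign files fail loudly instead of parsing silently.

artifact_header <- function(kind) sprintf("# mshbm %s v1", kind)

check_header <- function(path, kind) {
  line <- readLines(path, n = 1L)
  if (length(line) == 0L || !identical(line, artifact_header(kind)))
    stopf("%s: expected header '%s', found '%s'", path, artifact_header(kind),
          if (length(line)) line else "<empty file>")
}

#' Write / read a cortical graph
#'
#' Edge-list text plus a per-vertex hemisphere/mask table, with a versioned
#' header. Round-trips losslessly.
#'
#' @param graph A `cortical_graph`.
#' @param path File path.
#' @return `read_graph` returns a `cortical_graph`.
#' @export
write_graph <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(artifact_header("graph"), con)
  writeLines(sprintf("n_vertices=%d topology=%s", graph$n_vertices,
                     graph$topology), con)
  writeLines("# vertex hemisphere mask", con)
  writeLines(sprintf("%d %s %d", seq_len(graph$n_vertices),
                     as.character(graph$hemisphere),
                     as.integer(graph$cortex_mask)), con)
  writeLines("# edges", con)
  writeLines(sprintf("%d %d", graph$edges[, 1L], graph$edges[, 2L]), con)
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path) {
  check_header(path, "graph")
  lines <- readLines(path)
  meta <- strsplit(lines[2L], " ")[[1L]]
  n <- as.integer(sub("n_vertices=", "", meta[1L]))
  topology <- sub("topology=", "", meta[2L])
  if (is.na(n)) stopf("%s: malformed metadata line 2", path)
  vtab <- lines[4:(3L + n)]
  parts <- do.call(rbind, strsplit(vtab, " "))
  if (nrow(parts) != n || ncol(parts) != 3L) stopf("%s: truncated vertex table", path)
  estart <- 5L + n
  elines <- lines[estart:length(lines)]
  ep <- do.call(rbind, strsplit(elines, " "))
  edges <- cbind(as.integer(ep[, 1L]), as.integer(ep[, 2L]))
  if (anyNA(edges)) stopf("%s: malformed edge list", path)
  structure(
    list(n_vertices = n, edges = edges,
         hemisphere = factor(parts[, 2L], levels = c("L", "R")),
         cortex_mask = parts[, 3L] == "1",
         topology = topology,
         neighbors = adjacency_list(edges, n)),
    class = "cortical_graph"
  )
}

#' Write / read run time-series matrices
#'
#' Tab-separated frames-by-vertices and frames-by-ROIs matrices in one
#' file, full double precision.
#' @param run A `run_time_series`.
#' @param path File path.
#' @export
write_run <- function(run, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(artifact_header("run"), con)
  writeLines(sprintf("subject=%s session=%s T=%d V=%d R=%d tr=%s",
                     format(run$subject_id), format(run$session_id),
                     nrow(run$vertex_ts), ncol(run$vertex_ts),
                     ncol(run$roi_ts), format(run$tr_seconds)), con)
  write_mat <- function(m) writeLines(apply(m, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")), con)
  writeLines("# vertex_ts", con); write_mat(run$vertex_ts)
  writeLines("# roi_ts", con); write_mat(run$roi_ts)
  invisible(path)
}

#' @rdname write_run
#' @export
read_run <- function(path) {
  check_header(path, "run")
  lines <- readLines(path)
  kv <- strsplit(lines[2L], " ")[[1L]]
  get <- function(key) sub(paste0(key, "="), "", kv[startsWith(kv, paste0(key, "="))])
  Tn <- as.integer(get("T")); V <- as.integer(get("V")); R <- as.integer(get("R"))
  if (anyNA(c(Tn, V, R))) stopf("%s: malformed metadata", path)
  parse_block <- function(start, n, p) {
    block <- lines[start:(start + n - 1L)]
    m <- do.call(rbind, lapply(strsplit(block, "\t"), as.numeric))
    if (!all(dim(m) == c(n, p)) || anyNA(m)) stopf("%s: truncated matrix block", path)
    m
  }
  if (length(lines) < 4L + 2L * Tn) stopf("%s: truncated file", path)
  structure(
    list(subject_id = get("subject"), session_id = get("session"),
         vertex_ts = parse_block(4L, Tn, V),
         roi_ts = parse_block(5L + Tn, Tn, R),
         tr_seconds = as.numeric(get("tr"))),
    class = "run_time_series"
  )
}

#' Write / read a parcellation with its lookup table
#'
#' One integer label per line plus a FreeSurfer-style LUT block
#' (index, name, R, G, B, A). The LUT must list exactly K networks.
#'
#' @param labels Integer per-vertex labels in 0..K.
#' @param K Number of networks.
#' @param path File path.
#' @param network_names Optional K names for the LUT.
#' @export
write_parcellation <- function(labels, K, path, network_names = NULL) {
  if (is.null(network_names))
    network_names <- sprintf("Network_%02d", seq_len(K))
  if (length(network_names) != K) stopf("LUT needs exactly K=%d names", K)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(artifact_header("parcellation"), con)
  writeLines(sprintf("V=%d K=%d", length(labels), K), con)
  writeLines("# lut: index name R G B A", con)
  cols <- floor(seq(40, 255, length.out = K))
  writeLines(sprintf("%d %s %d %d %d 255", seq_len(K), network_names,
                     cols, rev(cols), floor((cols + rev(cols)) / 2)), con)
  writeLines("# labels", con)
  writeLines(sprintf("%d", labels), con)
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path) {
  check_header(path, "parcellation")
  lines <- readLines(path)
  kv <- strsplit(lines[2L], " ")[[1L]]
  V <- as.integer(sub("V=", "", kv[1L])); K <- as.integer(sub("K=", "", kv[2L]))
  lut <- lines[4:(3L + K)]
  lut_parts <- strsplit(lut, " ")
  if (length(lut_parts) != K || any(lengths(lut_parts) != 6L))
    stopf("%s: LUT entry count does not match K=%d", path, K)
  labels <- as.integer(lines[(5L + K):length(lines)])
  if (length(labels) != V || anyNA(labels)) stopf("%s: truncated label block", path)
  if (any(labels < 0L | labels > K)) stopf("%s: labels outside 0..K", path)
  list(labels = labels, K = K,
       network_names = vapply(lut_parts, `[[`, character(1), 2L))
}

#' Write / read a stimulation design as CSV
#' @param design A `stim_design`.
#' @param path File path.
#' @export
write_design <- function(design, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(artifact_header("design"), con)
  writeLines(sprintf("discard_frames=%d", design$discard_frames), con)
  writeLines("onset,duration,kind", con)
  writeLines(sprintf("%d,%d,%s", design$block_onsets, design$block_durations,
                     design$block_kinds), con)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  check_header(path, "design")
  lines <- readLines(path)
  discard <- as.integer(sub("discard_frames=", "", lines[2L]))
  if (is.na(discard) || !identical(lines[3L], "onset,duration,kind"))
    stopf("%s: malformed design header", path)
  rows <- strsplit(lines[-(1:3)], ",")
  if (any(lengths(rows) != 3L)) stopf("%s: malformed design row", path)
  stim_design(as.integer(vapply(rows, `[[`, character(1), 2L)),
              vapply(rows, `[[`, character(1), 3L), discard)
}

#' Write / read a connectivity profile as sparse triplets
#' @param profile A `connectivity_profile`.
#' @param path File path.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(artifact_header("profile"), con)
  m <- profile$matrix
  writeLines(sprintf("V=%d R=%d top_fraction=%s n_kept=%d subject=%s session=%s",
                     nrow(m), ncol(m), format(profile$top_fraction),
                     profile$n_kept, format(profile$subject_id),
                     format(profile$session_id)), con)
  tr <- Matrix::summary(m)
  writeLines("vertex roi value", con)
  writeLines(sprintf("%d %d %.17g", tr$i, tr$j, tr$x), con)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  check_header(path, "profile")
  lines <- readLines(path)
  kv <- strsplit(lines[2L], " ")[[1L]]
  get <- function(key) sub(paste0(key, "="), "", kv[startsWith(kv, paste0(key, "="))])
  V <- as.integer(get("V")); R <- as.integer(get("R"))
  tr <- do.call(rbind, strsplit(lines[-(1:3)], " "))
  if (ncol(tr) != 3L) stopf("%s: malformed triplet row", path)
  m <- Matrix::sparseMatrix(i = as.integer(tr[, 1L]), j = as.integer(tr[, 2L]),
                            x = as.numeric(tr[, 3L]), dims = c(V, R))
  structure(
    list(matrix = m, n_kept = as.integer(get("n_kept")),
         top_fraction = as.numeric(get("top_fraction")),
         mask = Matrix::rowSums(m^2) > 0,
         subject_id = get("subject"), session_id = get("session")),
    class = "connectivity_profile"
  )
}

#' Write / read a trained MS-HBM model as JSON
#'
#' Single self-describing container: arrays plus metadata (K, R, V,
#' hyperparameters, training tag). Numeric arrays round-trip at full
#' precision.
#'
#' @param params An `mshbm_params`.
#' @param path File path (`.json`).
#' @param trained_on Free-text tag recording the training cohort.
#' @export
write_model <- function(params, path, trained_on = "synthetic") {
  obj <- list(
    format = "mshbm-model-v1",
    K = params$K, R = params$R, V = params$V,
    c_smooth = params$c_smooth, theta_alpha = params$theta_alpha,
    kappa = params$kappa, epsilon = params$epsilon, sigma = params$sigma,
    mu = params$mu, theta = params$theta, mask = params$mask,
    converged = params$converged, trained_on = trained_on
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "mshbm-model-v1"))
    stopf("%s: not an mshbm model container", path)
  as_mat <- function(x, nr, nc) {
    if (is.matrix(x)) x else matrix(unlist(x), nr, nc, byrow = TRUE)
  }
  structure(
    list(mu = as_mat(obj$mu, obj$K, obj$R),
         epsilon = as.numeric(obj$epsilon), sigma = as.numeric(obj$sigma),
         kappa = as.numeric(obj$kappa),
         theta = as_mat(obj$theta, obj$V, obj$K),
         c_smooth = obj$c_smooth, K = obj$K, R = obj$R, V = obj$V,
         theta_alpha = obj$theta_alpha, objective_trace = numeric(0),
         subject_labels = NULL, converged = obj$converged,
         mask = as.logical(obj$mask)),
    class = "mshbm_params"
  )
}
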