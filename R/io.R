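#' Write a contact or symmetrized map as TSV
#'
#' Plain TSV with a header row and leading column of indices (global residue
#' indices for a `contact_map`, author residue numbers for a
#' `symmetrized_map`) and `#`-prefixed metadata lines. Numbers are formatted
#' with full precision (`%.17g`) so a write/read round trip is lossless and
#' re-running a deterministic pipeline yields byte-identical files.
#'
#' @param map a `contact_map` or `symmetrized_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_map_tsv <- function(map, path) {
  M <- map$matrix
  labels <- if (inherits(map, "symmetrized_map")) map$frame_resno else 0:(nrow(M) - 1)
  meta <- c(
    paste0("# class=", class(map)[1]),
    paste0("# mode=", map$mode),
    paste0("# cutoff=", fmt_num(map$cutoff)),
    paste0("# normalized=", isTRUE(map$normalized))
  )
  if (!is.null(map$n_frames)) meta <- c(meta, paste0("# n_frames=", map$n_frames))
  header <- paste(c("", labels), collapse = "\t")
  rows <- vapply(seq_len(nrow(M)), function(i) {
    paste(c(labels[i], fmt_num(M[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(meta, header, rows), path)
  invisible(path)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Read a TSV map written by [write_map_tsv()]
#'
#' @param path TSV path.
#' @return A list with `matrix`, `labels`, and the metadata fields; the
#'   class recorded in the file is restored.
#' @export
read_map_tsv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  body <- lines[!grepl("^#", lines)]
  header <- strsplit(body[1], "\t")[[1]][-1]
  rows <- strsplit(body[-1], "\t")
  M <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
  dimnames(M) <- list(header, header)
  out <- list(matrix = M, labels = as.integer(header),
              mode = meta$mode, cutoff = as.numeric(meta$cutoff),
              normalized = identical(meta$normalized, "TRUE"),
              n_frames = if (!is.null(meta$n_frames)) as.numeric(meta$n_frames))
  class(out) <- c(meta$class %||% "map_table", "map_table")
  if (identical(meta$class, "symmetrized_map")) out$frame_resno <- out$labels
  out
}

#' Write a map in Matrix Market format
#'
#' Sparse coordinate MTX via the Matrix package, for large mostly-empty
#' contact matrices.
#'
#' @param map a `contact_map` or `symmetrized_map`.
#' @param path output `.mtx` path.
#' @return `path`, invisibly.
#' @export
write_map_mtx <- function(map, path) {
  m <- Matrix::Matrix(map$matrix, sparse = TRUE)
  m <- methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  Matrix::writeMM(m, path)
  invisible(path)
}

#' Write a tail profile as two-column TSV
#'
#' @param profile a [terminal_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  lines <- c(
    paste0("# terminal_residue=", attr(profile, "terminal_residue")),
    paste0("# zeroed=", paste(attr(profile, "zeroed"), collapse = ",")),
    "resno\tscore",
    paste(profile$resno, fmt_num(profile$score), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a trajectory segment as multi-model PDB
#'
#' One MODEL/ENDMDL block per frame, re-readable with [read_trajectory()].
#'
#' @param segment a [run_langevin()] segment.
#' @param system the matching [molecular_system()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(segment, system, path) {
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (f in seq_len(segment$n_frames)) {
    sys_f <- set_coords(system, matrix(segment$coords[f, , ], ncol = 3))
    write_structure(sys_f, tmp)
    body <- readLines(tmp)
    body <- body[!grepl("^END$", body)]
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(body, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read trajectory frames
#'
#' Multi-model PDB (via bio3d, dispatched on extension) or DCD
#' (`bio3d::read.dcd`). XTC is not supported; convert externally to
#' multi-model PDB or DCD.
#'
#' @param path trajectory file (`.pdb` multi-model, or `.dcd`).
#' @param segment_id id for the resulting segment.
#' @return A `trajectory_segment` with the frames read (no simulation
#'   metadata).
#' @export
read_trajectory <- function(path, segment_id = basename(path)) {
  ext <- tolower(tools::file_ext(path))
  xyz <- if (ext == "dcd") {
    bio3d::read.dcd(path, verbose = FALSE)
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    pdb$xyz
  }
  xyz <- unclass(xyz)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_frames <- nrow(xyz)
  n_atoms <- ncol(xyz) / 3
  coords <- array(NA_real_, c(n_frames, n_atoms, 3))
  for (d in 1:3) coords[, , d] <- xyz[, seq(d, ncol(xyz), by = 3), drop = FALSE]
  structure(list(coords = coords, step_index = seq_len(n_frames) - 1L,
                 n_frames = n_frames, segment_id = segment_id,
                 role = "production", seed = NA_integer_,
                 mobile = rep(TRUE, n_atoms),
                 kinetic_temperature = NA_real_, frame_temperature = NULL,
                 params = NULL),
            class = "trajectory_segment")
}
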