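#' Read a tetrahedral mesh from an INP-subset file
#'
#' Parses the plain-text INP dialect used by common FE preprocessors,
#' restricted to `*NODE`, `*ELEMENT` (`TYPE=C3D4`, optional `ELSET=` naming
#' the material region), `*NSET` and `*ELSET` blocks. `*ELSET` blocks
#' reassign the material region of the listed elements to the set name.
#' Unknown keywords are skipped with a warning; malformed data lines raise an
#' error carrying the line number.
#'
#' @param path Path to the INP file.
#' @return A [tet_mesh()].
#' @export
read_inp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  node_id <- integer(0); node_xyz <- list()
  elem_id <- integer(0); elem_nodes <- list(); elem_region <- character(0)
  nsets <- list(); elsets <- list()
  mode <- "none"; set_name <- NULL; generate <- FALSE
  parse_keyword <- function(line) {
    parts <- strsplit(sub("^\\*", "", line), ",")[[1]]
    kw <- toupper(trimws(parts[1]))
    opts <- list()
    for (p in parts[-1]) {
      kv <- strsplit(p, "=")[[1]]
      key <- toupper(trimws(kv[1]))
      opts[[key]] <- if (base::length(kv) > 1) trimws(kv[2]) else TRUE
    }
    list(kw = kw, opts = opts)
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (line == "" || startsWith(line, "**")) next
    if (startsWith(line, "*")) {
      k <- parse_keyword(line)
      generate <- isTRUE(k$opts[["GENERATE"]] == TRUE) || identical(k$opts[["GENERATE"]], "YES")
      if (k$kw == "NODE") {
        mode <- "node"
      } else if (k$kw == "ELEMENT") {
        type <- toupper(k$opts[["TYPE"]] %||% "")
        if (type != "C3D4") {
          warn(sprintf("line %d: skipping unsupported element type `%s`", i, type))
          mode <- "skip"
        } else {
          mode <- "element"
          set_name <- k$opts[["ELSET"]] %||% "bone"
        }
      } else if (k$kw == "NSET") {
        mode <- "nset"
        set_name <- k$opts[["NSET"]] %||% stop_input("line %d: NSET without a name", i)
      } else if (k$kw == "ELSET") {
        mode <- "elset"
        set_name <- k$opts[["ELSET"]] %||% stop_input("line %d: ELSET without a name", i)
      } else {
        warn(sprintf("line %d: skipping unknown keyword *%s", i, k$kw))
        mode <- "skip"
      }
      next
    }
    vals <- suppressWarnings(as.numeric(strsplit(line, ",")[[1]]))
    if (any(is.na(vals))) {
      if (mode == "skip") next
      stop_input("line %d: malformed data line `%s`", i, lines[i])
    }
    if (mode == "node") {
      if (base::length(vals) != 4) stop_input("line %d: node line needs id,x,y,z", i)
      node_id <- c(node_id, as.integer(vals[1]))
      node_xyz[[base::length(node_xyz) + 1]] <- vals[2:4]
    } else if (mode == "element") {
      if (base::length(vals) != 5) stop_input("line %d: C3D4 element line needs id + 4 node ids", i)
      elem_id <- c(elem_id, as.integer(vals[1]))
      elem_nodes[[base::length(elem_nodes) + 1]] <- as.integer(vals[2:5])
      elem_region <- c(elem_region, set_name)
    } else if (mode %in% c("nset", "elset")) {
      ids <- if (generate) seq.int(vals[1], vals[2], by = if (base::length(vals) >= 3) vals[3] else 1) else as.integer(vals)
      target <- if (mode == "nset") "nsets" else "elsets"
      cur <- get(target)[[set_name]] %||% integer(0)
      if (mode == "nset") nsets[[set_name]] <- c(cur, as.integer(ids))
      else elsets[[set_name]] <- c(cur, as.integer(ids))
    }
  }
  if (base::length(node_id) == 0) stop_input("no *NODE block found in %s", path)
  if (anyDuplicated(node_id)) stop_input("duplicate node ids in %s", path)
  ord <- order(node_id)
  nodes <- do.call(rbind, node_xyz)[ord, , drop = FALSE]
  rownames(nodes) <- node_id[ord]
  remap <- setNames(seq_along(node_id), node_id[ord])
  elems_ext <- do.call(rbind, elem_nodes)
  missing_ref <- !as.character(elems_ext) %in% names(remap)
  if (any(missing_ref)) {
    stop_input("element(s) reference missing node id(s): %s",
               paste(unique(as.vector(elems_ext)[missing_ref])[1:min(5, sum(missing_ref))], collapse = ", "))
  }
  elems <- matrix(remap[as.character(elems_ext)], ncol = 4)
  eord <- order(elem_id)
  elems <- elems[eord, , drop = FALSE]
  regions <- elem_region[eord]
  # ELSET blocks override region labels by element id
  for (nm in names(elsets)) {
    pos <- match(elsets[[nm]], elem_id[eord])
    if (any(is.na(pos))) stop_input("ELSET %s references missing element id(s)", nm)
    regions[pos] <- nm
  }
  node_sets <- lapply(nsets, function(ids) {
    bad <- !as.character(ids) %in% names(remap)
    if (any(bad)) stop_input("NSET references missing node id(s): %s",
                             paste(unique(ids[bad]), collapse = ", "))
    unname(remap[as.character(ids)])
  })
  tet_mesh(nodes, elems, regions, node_sets)
}

#' Write a tetrahedral mesh as an INP-subset file
#'
#' Emits `*NODE`, one `*ELEMENT, TYPE=C3D4, ELSET=<region>` block per
#' material region, and one `*NSET` block per node set, in a deterministic
#' order so identical meshes produce byte-identical files.
#'
#' @param mesh A [tet_mesh()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_inp <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("*NODE", con)
  writeLines(sprintf("%d, %.9g, %.9g, %.9g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  for (reg in unique(mesh$regions)) {
    writeLines(sprintf("*ELEMENT, TYPE=C3D4, ELSET=%s", reg), con)
    ids <- which(mesh$regions == reg)
    e <- mesh$elements[ids, , drop = FALSE]
    writeLines(sprintf("%d, %d, %d, %d, %d", ids, e[, 1], e[, 2], e[, 3], e[, 4]), con)
  }
  for (nm in names(mesh$node_sets)) {
    writeLines(sprintf("*NSET, NSET=%s", nm), con)
    ids <- mesh$node_sets[[nm]]
    for (chunk in split(ids, ceiling(seq_along(ids) / 8))) {
      writeLines(paste(chunk, collapse = ", "), con)
    }
  }
  invisible(path)
}
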