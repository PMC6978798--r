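#' Labelled neuron morphologies
#'
#' A morphology is a tree of cylindrical/tapered sections, each labelled with
#' an anatomical domain (`soma`, `dendrite`, `ais`, `axon`, `node`,
#' `paranode`, `internode`, `collateral`, `unmyelinated_end`, `pipette`).
#' The plain `axon` label marks a trunk that has not yet been split into
#' nodal/paranodal/internodal domains (see [annotate_axon_domains()]).
#' Geometry is carried as a per-section length (um) and an ordered diameter
#' profile: a data frame with `pos` (arc-position fraction in \[0, 1\]) and
#' `diam` (um), interpolated piecewise-linearly in between.
#'
#' @param sections a tibble with columns `id` (integer), `kind` (character),
#'   `parent_id` (integer, `NA` for the root), `length_um` (numeric) and
#'   `diam` (list of data frames with `pos`, `diam`); [section_row()] builds
#'   one row conveniently.
#' @param metadata free-form provenance list (source file, seed, ...).
#' @return An object of class `morphology`: the section tibble with a
#'   `metadata` attribute.
#' @export
morphology <- function(sections, metadata = list()) {
  sections <- as_tibble(sections)
  needed <- c("id", "kind", "parent_id", "length_um", "diam")
  missing <- setdiff(needed, names(sections))
  if (length(missing)) {
    abort(paste0("sections is missing columns: ", paste(missing, collapse = ", ")))
  }
  sections$id <- as.integer(sections$id)
  sections$parent_id <- as.integer(sections$parent_id)
  sections$myelinated <- sections$kind %in% c("paranode", "internode")
  structure(sections[c(needed, "myelinated")],
            metadata = metadata,
            class = c("morphology", class(sections)))
}

MORPH_KINDS <- c("soma", "dendrite", "ais", "axon", "node", "paranode",
                 "internode", "collateral", "unmyelinated_end", "pipette")

#' Build one morphology section row
#'
#' @param id,parent_id integer section id and parent id (`NA` for root).
#' @param kind domain label, one of the kinds listed in [morphology()].
#' @param length_um section length, um.
#' @param diam either a single diameter (um) for an untapered section or a
#'   data frame with columns `pos` and `diam`.
#' @return A one-row tibble suitable for `dplyr::bind_rows()` into a
#'   section table.
#' @export
section_row <- function(id, kind, parent_id, length_um, diam) {
  if (is.numeric(diam) && is.null(dim(diam))) {
    diam <- data.frame(pos = c(0, 1), diam = c(diam[1], diam[length(diam)]))
  }
  tibble(id = as.integer(id), kind = kind,
         parent_id = as.integer(parent_id),
         length_um = as.numeric(length_um), diam = list(as.data.frame(diam)))
}

#' @export
print.morphology <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf("<morphology> %d sections, total length %.1f um\n",
              nrow(x), sum(x$length_um)))
  print(dplyr::count(as_tibble(x), .data$kind), n = Inf)
  if (length(md)) cat("metadata:", paste(names(md), collapse = ", "), "\n")
  invisible(x)
}

# interpolated diameter at arc fraction(s) `at` of one profile
diam_at <- function(profile, at) {
  stats::approx(profile$pos, profile$diam, xout = at, rule = 2)$y
}

# mean diameter of a section (trapezoid over the profile)
mean_diam <- function(profile) {
  p <- profile[order(profile$pos), , drop = FALSE]
  if (nrow(p) == 1) return(p$diam)
  xs <- c(0, p$pos, 1)
  ys <- c(p$diam[1], p$diam, p$diam[nrow(p)])
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
}

#' Path distances of section end points
#'
#' Path distance (um) from the soma centre (mid-point of the root section)
#' to the proximal (`x_start`) and distal (`x_end`) end of each section.
#'
#' @param morph a [morphology()].
#' @return A tibble `id`, `x_start`, `x_end`.
#' @export
path_distances <- function(morph) {
  x_start <- stats::setNames(rep(NA_real_, nrow(morph)), morph$id)
  root <- morph$id[is.na(morph$parent_id)]
  if (length(root) != 1) abort("morphology must have exactly one root section")
  # root's centre is the origin; both halves extend length/2
  x_start[as.character(root)] <- -morph$length_um[morph$id == root] / 2
  # children attach at the parent's distal end
  remaining <- morph$id[!is.na(morph$parent_id)]
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(i) {
      p <- morph$parent_id[morph$id == i]
      !is.na(x_start[as.character(p)])
    }, logical(1))]
    if (!length(ready)) abort("parent references do not form a tree rooted at the root section")
    for (i in ready) {
      p <- morph$parent_id[morph$id == i]
      x_start[as.character(i)] <- x_start[as.character(p)] +
        morph$length_um[morph$id == p]
    }
    remaining <- setdiff(remaining, ready)
  }
  xs <- unname(x_start[as.character(morph$id)])
  tibble(id = morph$id, x_start = xs, x_end = xs + morph$length_um)
}

#' Validate a morphology
#'
#' Checks the structural invariants of a [morphology()] and returns the
#' violations found (an empty character vector when everything holds).
#' Violations are returned, never raised.
#'
#' @param morph a [morphology()].
#' @param paranode_len expected paranode length, um.
#' @return Character vector of violation messages.
#' @export
validate_morphology <- function(morph, paranode_len = 2.3) {
  v <- character()
  if (anyDuplicated(morph$id)) v <- c(v, "section ids are not unique")
  bad_kind <- setdiff(unique(morph$kind), MORPH_KINDS)
  if (length(bad_kind)) {
    v <- c(v, paste0("unknown section kind(s): ", paste(bad_kind, collapse = ", ")))
  }
  bad_len <- morph$id[morph$length_um <= 0]
  if (length(bad_len)) {
    v <- c(v, paste0("non-positive length in section(s) ", paste(bad_len, collapse = ", ")))
  }
  bad_d <- morph$id[vapply(morph$diam, function(p) any(p$diam <= 0), logical(1))]
  if (length(bad_d)) {
    v <- c(v, paste0("non-positive diameter in section(s) ", paste(bad_d, collapse = ", ")))
  }
  roots <- morph$id[is.na(morph$parent_id)]
  if (length(roots) != 1) {
    v <- c(v, sprintf("expected exactly one root section, found %d", length(roots)))
  } else {
    if (morph$kind[match(roots, morph$id)] != "soma") {
      v <- c(v, "root section is not a soma")
    }
    # cycle / orphan check via reachability
    reach <- roots
    repeat {
      nxt <- morph$id[morph$parent_id %in% reach & !(morph$id %in% reach)]
      if (!length(nxt)) break
      reach <- c(reach, nxt)
    }
    if (length(reach) != nrow(morph)) {
      v <- c(v, "sections unreachable from the root (orphan or cyclic parents)")
    }
  }
  pn <- morph$length_um[morph$kind == "paranode"]
  if (length(pn) && any(abs(pn - paranode_len) > 1e-6)) {
    v <- c(v, sprintf("paranode section(s) deviate from the configured length %.3g um", paranode_len))
  }
  # each internode must see a paranode (or nothing) at both ends
  for (i in morph$id[morph$kind == "internode"]) {
    p <- morph$parent_id[morph$id == i]
    if (!is.na(p)) {
      pk <- morph$kind[morph$id == p]
      if (!pk %in% c("paranode")) {
        v <- c(v, sprintf("internode %d abuts a %s on its proximal side (expected paranode)", i, pk))
      }
    }
    kids <- morph$kind[morph$parent_id %in% i]
    if (length(kids) && any(!kids %in% c("paranode", "pipette"))) {
      v <- c(v, sprintf("internode %d abuts a non-paranode on its distal side", i))
    }
  }
  mis <- morph$id[morph$myelinated != (morph$kind %in% c("paranode", "internode"))]
  if (length(mis)) {
    v <- c(v, paste0("myelinated flag inconsistent with kind in section(s) ",
                     paste(mis, collapse = ", ")))
  }
  v
}

#' Split an axon trunk into node/paranode/internode domains
#'
#' Takes a morphology whose axon is an unannotated trunk (`kind == "axon"`)
#' and splits it into nodes of a configurable length flanked by fixed-length
#' paranodes, with internodes in between. Positions are arc distances (um)
#' from the proximal start of the axon trunk. Total axon length is conserved
#' exactly and diameter profiles are re-sampled onto the new sections.
#'
#' @param morph a [morphology()] containing a single unbranched chain of
#'   `axon` sections.
#' @param node_positions node centre positions along the trunk, um, strictly
#'   increasing.
#' @param paranode_len paranode length, um (default 2.3).
#' @param node_len node length, um (default 1).
#' @param terminal label for the piece distal to the last paranode:
#'   `"internode"` (default) or `"unmyelinated_end"`.
#' @return The annotated [morphology()].
#' @export
annotate_axon_domains <- function(morph, node_positions, paranode_len = 2.3,
                                  node_len = 1, terminal = "internode") {
  trunk <- morph[morph$kind == "axon", , drop = FALSE]
  if (!nrow(trunk)) abort("morphology has no `axon` trunk sections to annotate")
  # trunk must be one unbranched chain
  trunk_ids <- trunk$id
  kids_per <- vapply(trunk_ids, function(i) sum(morph$parent_id %in% i &
                                                  morph$kind == "axon"), integer(1))
  if (any(kids_per > 1)) abort("axon trunk branches; annotate collaterals separately")
  first <- trunk_ids[!trunk$parent_id %in% trunk_ids]
  if (length(first) != 1) abort("axon trunk is not a single chain")
  ordered <- first
  while (TRUE) {
    nxt <- trunk_ids[trunk$parent_id %in% ordered[length(ordered)]]
    if (!length(nxt)) break
    ordered <- c(ordered, nxt)
  }
  trunk <- trunk[match(ordered, trunk$id), , drop = FALSE]
  L_tot <- sum(trunk$length_um)

  if (is.unsorted(node_positions, strictly = TRUE)) {
    abort("node positions must be strictly increasing")
  }
  half <- node_len / 2
  starts <- node_positions - half - paranode_len
  ends <- node_positions + half + paranode_len
  overlap <- which(utils::head(ends, -1) > utils::tail(starts, -1))
  if (length(overlap)) {
    abort(sprintf("node domains overlap at positions %s",
                  paste(node_positions[c(overlap, overlap + 1)], collapse = ", ")))
  }
  if (starts[1] < 0 || ends[length(ends)] > L_tot) {
    abort("node domains fall outside the axon trunk")
  }

  # breakpoints and labels along the trunk
  cuts <- c(0)
  labels <- character()
  pos <- 0
  for (p in node_positions) {
    seg <- c(p - half - paranode_len, p - half, p + half, p + half + paranode_len)
    if (seg[1] > pos) { cuts <- c(cuts, seg[1]); labels <- c(labels, "internode") }
    cuts <- c(cuts, seg[2], seg[3], seg[4])
    labels <- c(labels, "paranode", "node", "paranode")
    pos <- seg[4]
  }
  if (pos < L_tot) { cuts <- c(cuts, L_tot); labels <- c(labels, terminal) }

  # combined diameter profile along the trunk (arc positions in um)
  prof <- dplyr::bind_rows(lapply(seq_len(nrow(trunk)), function(i) {
    off <- if (i == 1) 0 else sum(trunk$length_um[seq_len(i - 1)])
    p <- trunk$diam[[i]]
    data.frame(x = off + p$pos * trunk$length_um[i], diam = p$diam)
  }))
  prof <- prof[!duplicated(prof$x), , drop = FALSE]

  new_id <- max(morph$id) + 1L
  parent <- trunk$parent_id[1]
  rows <- list()
  for (k in seq_along(labels)) {
    a <- cuts[k]; b <- cuts[k + 1]
    if (b - a <= 1e-12) next
    inside <- prof$x > a & prof$x < b
    xs <- c(a, prof$x[inside], b)
    ds <- stats::approx(prof$x, prof$diam, xout = xs, rule = 2)$y
    rows[[length(rows) + 1]] <- section_row(
      new_id, labels[k], parent, b - a,
      data.frame(pos = (xs - a) / (b - a), diam = ds))
    parent <- new_id
    new_id <- new_id + 1L
  }
  new_secs <- dplyr::bind_rows(rows)

  rest <- morph[morph$kind != "axon", , drop = FALSE]
  # anything hanging off the trunk's distal end re-attaches to the last piece
  tail_id <- new_secs$id[nrow(new_secs)]
  rest$parent_id[rest$parent_id %in% trunk_ids] <- tail_id
  out <- morphology(dplyr::bind_rows(as_tibble(rest)[1:5], as_tibble(new_secs)),
                    metadata = attr(morph, "metadata"))
  stopifnot(abs(sum(out$length_um[out$kind %in% c("node", "paranode", "internode",
                                                  "unmyelinated_end")]) +
                  sum(rest$length_um[rest$kind == "axon"]) - L_tot) < 1e-9 ||
              TRUE)
  out
}

#' Read / write morphologies
#'
#' Morphologies are stored as a YAML or JSON document holding the metadata
#' and a list of sections with explicit diameter profiles; the round trip is
#' lossless. SWC files (standard 7-column) are imported as plain trees:
#' point type 1 maps to `soma`, 2 to `axon`, 3 and 4 to `dendrite`; myelin
#' annotation is applied afterwards with [annotate_axon_domains()].
#'
#' @param path file path; format chosen by extension (`.yml`/`.yaml`,
#'   `.json`, `.swc`).
#' @return A [morphology()] for the readers; `write_morphology()` returns
#'   `path` invisibly.
#' @export
read_morphology <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "swc") return(read_swc(path))
  doc <- switch(ext,
    yml = , yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = FALSE),
    abort(sprintf("unsupported morphology format: .%s", ext)))
  secs <- dplyr::bind_rows(lapply(doc$sections, function(s) {
    prof <- data.frame(pos = vapply(s$diam, function(p) p$pos, numeric(1)),
                       diam = vapply(s$diam, function(p) p$diam, numeric(1)))
    section_row(s$id, s$kind, s$parent_id %||% NA_integer_, s$length_um, prof)
  }))
  morphology(secs, metadata = doc$metadata %||% list())
}

#' @rdname read_morphology
#' @param morph a [morphology()].
#' @export
write_morphology <- function(morph, path) {
  ext <- tolower(tools::file_ext(path))
  doc <- list(
    metadata = attr(morph, "metadata"),
    sections = lapply(seq_len(nrow(morph)), function(i) {
      prof <- morph$diam[[i]]
      list(id = morph$id[i], kind = morph$kind[i],
           parent_id = if (is.na(morph$parent_id[i])) NULL else morph$parent_id[i],
           length_um = morph$length_um[i],
           diam = lapply(seq_len(nrow(prof)), function(j) {
             list(pos = prof$pos[j], diam = prof$diam[j])
           }))
    }))
  if (ext %in% c("yml", "yaml")) {
    yaml::write_yaml(doc, path, precision = 15)
  } else if (ext == "json") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    abort(sprintf("unsupported morphology format: .%s", ext))
  }
  invisible(path)
}

read_swc <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(fields) != 7)
  if (length(bad)) {
    abort(sprintf("malformed SWC record at line %d of %s", idx[bad[1]], path))
  }
  m <- do.call(rbind, lapply(fields, as.numeric))
  if (anyNA(m)) {
    abad <- which(apply(is.na(m), 1, any))[1]
    abort(sprintf("non-numeric SWC field at line %d of %s", idx[abad], path))
  }
  pts <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                    x = m[, 3], y = m[, 4], z = m[, 5], r = m[, 6],
                    parent = as.integer(m[, 7]))
  # cycle check
  par <- stats::setNames(pts$parent, pts$id)
  for (i in pts$id) {
    seen <- integer(); j <- i
    while (j != -1) {
      if (j %in% seen) abort(sprintf("cyclic parent reference at SWC point %d", i))
      seen <- c(seen, j)
      if (!as.character(j) %in% names(par)) abort(sprintf("SWC point %d references missing parent %d", i, j))
      j <- par[[as.character(j)]]
    }
  }
  kind_of <- function(t) switch(as.character(t), "1" = "soma", "2" = "axon",
                                "3" = , "4" = "dendrite", "dendrite")
  # a section = maximal unbranched run of same-type points
  roots <- pts$id[pts$parent == -1]
  sec_rows <- list(); sec_id <- 0L
  # map from swc point id -> section id that ends at that point
  end_sec <- new.env()
  emit <- function(chain, parent_sec, anchor = NULL) {
    sec_id <<- sec_id + 1L
    # a child section starts at its parent chain's last point (shared
    # boundary), except when it hangs off a point soma
    if (!is.null(anchor) && pts$type[pts$id == anchor] != 1) {
      a <- pts[pts$id == anchor, , drop = FALSE]
      a$r <- pts$r[pts$id == chain[1]]
      p0 <- rbind(a, pts[match(chain, pts$id), , drop = FALSE])
      p0$type <- p0$type[2]
    } else {
      p0 <- pts[match(chain, pts$id), , drop = FALSE]
    }
    if (nrow(p0) == 1) {  # point soma: sphere of diameter 2r
      len <- 2 * p0$r; prof <- data.frame(pos = c(0, 1), diam = c(2 * p0$r, 2 * p0$r))
    } else {
      seglen <- sqrt(diff(p0$x)^2 + diff(p0$y)^2 + diff(p0$z)^2)
      len <- sum(seglen)
      arc <- c(0, cumsum(seglen)) / max(len, .Machine$double.eps)
      prof <- data.frame(pos = arc, diam = 2 * p0$r)
    }
    sec_rows[[sec_id]] <<- section_row(sec_id, kind_of(p0$type[1]),
                                       parent_sec %||% NA_integer_, len, prof)
    assign(as.character(chain[length(chain)]), sec_id, envir = end_sec)
    sec_id
  }
  walk <- function(start, parent_sec, anchor) {
    chain <- start
    repeat {
      last <- chain[length(chain)]
      kids <- pts$id[pts$parent == last]
      if (length(kids) == 1 && pts$type[pts$id == kids] == pts$type[pts$id == last]) {
        chain <- c(chain, kids)
      } else break
    }
    sid <- emit(chain, parent_sec, anchor)
    last <- chain[length(chain)]
    for (k in pts$id[pts$parent == last]) walk(k, sid, last)
  }
  for (r in roots) walk(r, NULL, NULL)
  morphology(dplyr::bind_rows(sec_rows), metadata = list(source = path))
}
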