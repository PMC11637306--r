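#' Axon morphologies as tidy node tables
#'
#' A morphology is a tibble of 3D points with per-point radius, one row per
#' node, in parent-before-child order. This mirrors the SWC interchange
#' format used by reconstruction software: each node has an integer `id`, a
#' `parent_id` (`NA` for the single root), coordinates in micrometers, a
#' `radius` in micrometers, and a structure `label` (one of `"soma"`,
#' `"axon"`, `"bouton"`, `"filopodium"`).
#'
#' @param nodes A data frame with columns `id`, `parent_id`, `x`, `y`, `z`,
#'   `radius`, `label`.
#' @param metadata Optional named list of provenance information.
#' @return A tibble of class `axon_morphology`.
#' @export
morphology <- function(nodes, metadata = list()) {
  nodes <- tibble::as_tibble(nodes)
  required <- c("id", "parent_id", "x", "y", "z", "radius", "label")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols) > 0) {
    abort(paste0("missing morphology columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(nodes) == 0) abort("morphology must contain at least one node")
  nodes <- validate_morphology_nodes(nodes)
  structure(nodes, metadata = metadata,
            class = c("axon_morphology", class(tibble::tibble())))
}

validate_morphology_nodes <- function(nodes) {
  if (any(!is.finite(nodes$x) | !is.finite(nodes$y) | !is.finite(nodes$z))) {
    abort("all coordinates must be finite")
  }
  if (any(!is.finite(nodes$radius) | nodes$radius <= 0)) {
    abort("all radii must be positive and finite")
  }
  roots <- which(is.na(nodes$parent_id))
  if (length(roots) != 1) {
    abort(sprintf("morphology must have exactly one root, found %d",
                  length(roots)), class = "axonwave_structure_error")
  }
  if (anyDuplicated(nodes$id)) abort("duplicate node ids")
  # topological sort: parents before children
  pos <- match(nodes$parent_id, nodes$id)
  if (any(is.na(pos) & !is.na(nodes$parent_id))) {
    abort("parent_id refers to a missing node",
          class = "axonwave_structure_error")
  }
  if (any(pos >= seq_len(nrow(nodes)), na.rm = TRUE)) {
    nodes <- toposort_nodes(nodes)
  }
  nodes
}

toposort_nodes <- function(nodes) {
  n <- nrow(nodes)
  order_out <- integer(0)
  placed <- rep(FALSE, n)
  repeat {
    ready <- which(!placed &
                     (is.na(nodes$parent_id) |
                        nodes$parent_id %in% nodes$id[placed]))
    if (length(ready) == 0) break
    order_out <- c(order_out, ready)
    placed[ready] <- TRUE
  }
  if (!all(placed)) abort("cycle detected in morphology",
                          class = "axonwave_structure_error")
  nodes[order_out, , drop = FALSE]
}

swc_type_codes <- c(soma = 1L, axon = 2L, bouton = 5L, filopodium = 6L)

#' Read a morphology from an SWC file
#'
#' Parses the standard 7-column SWC dialect (`id type x y z radius parent`,
#' `#` comments, radius in micrometers). Nodes are topologically sorted so
#' parents precede children.
#'
#' @param path Path to an SWC file.
#' @return An [morphology()] tibble.
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  body <- lines[keep]
  line_no <- which(keep)
  if (length(body) == 0) abort("SWC file contains no data lines")
  fields <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(fields, length, integer(1)) != 7)
  if (length(bad) > 0) {
    abort(sprintf("malformed SWC line %d: expected 7 columns",
                  line_no[bad[1]]), class = "axonwave_parse_error")
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                ncol = 7, byrow = TRUE)
  if (anyNA(mat)) {
    bad_row <- which(apply(is.na(mat), 1, any))[1]
    abort(sprintf("malformed SWC line %d: non-numeric field",
                  line_no[bad_row]), class = "axonwave_parse_error")
  }
  type <- as.integer(mat[, 2])
  label <- names(swc_type_codes)[match(type, swc_type_codes)]
  label[is.na(label)] <- "axon"
  nodes <- tibble::tibble(
    id = as.integer(mat[, 1]),
    parent_id = ifelse(mat[, 7] < 0, NA_integer_, as.integer(mat[, 7])),
    x = mat[, 3], y = mat[, 4], z = mat[, 5],
    radius = mat[, 6], label = label
  )
  morphology(nodes, metadata = list(source = path))
}

#' Write a morphology to an SWC file
#'
#' Radii and coordinates are serialized with enough significant digits that
#' `read_swc(write_swc(m))` reproduces the numeric content exactly.
#'
#' @param morph An [morphology()] object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_swc <- function(morph, path) {
  stopifnot(inherits(morph, "axon_morphology"))
  if (nrow(morph) == 0) abort("refusing to write an empty morphology")
  type <- unname(swc_type_codes[morph$label])
  type[is.na(type)] <- 0L
  lines <- sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                   morph$id, type, morph$x, morph$y, morph$z, morph$radius,
                   ifelse(is.na(morph$parent_id), -1L, morph$parent_id))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# SWC written by axonwave", lines), con)
  invisible(path)
}

#' Discretize a morphology into iso-potential compartments
#'
#' Each inter-node piece of the tree is split into sub-segments no longer
#' than `max_seg_len`, with the diameter linearly interpolated between the
#' two flanking nodes. Membrane area uses the frustum (truncated-cone)
#' lateral surface; axial resistance of a sub-segment is
#' `4 * Ra * L / (pi * d^2)` at its mean diameter, split into two halves so
#' that the coupling resistance between neighbours is the sum of the facing
#' halves.
#'
#' @param morph An [morphology()] object.
#' @param max_seg_len Maximum compartment length in micrometers (default 1).
#' @param ra Axial resistivity in Ohm cm, used for the stored half
#'   resistances (default 150).
#' @return A tibble of class `compartment_grid` with one row per compartment:
#'   `index`, `parent` (compartment index or `NA`), `path_pos` (center, um),
#'   `length` (um), `diameter` (um), `area` (um^2), `r_half` (MOhm),
#'   `label`, `branch_id`.
#' @export
discretize <- function(morph, max_seg_len = 1, ra = 150) {
  stopifnot(inherits(morph, "axon_morphology"), max_seg_len > 0, ra > 0)
  nodes <- tibble::as_tibble(morph)
  idx_of <- stats::setNames(seq_len(nrow(nodes)), nodes$id)

  comp <- list()
  # last compartment index assigned at each node (for connectivity)
  node_comp <- rep(NA_integer_, nrow(nodes))
  node_path <- rep(0, nrow(nodes))  # path distance from root
  counter <- 0L

  for (i in seq_len(nrow(nodes))) {
    if (is.na(nodes$parent_id[i])) next
    pidx <- idx_of[[as.character(nodes$parent_id[i])]]
    dx <- nodes$x[i] - nodes$x[pidx]
    dy <- nodes$y[i] - nodes$y[pidx]
    dz <- nodes$z[i] - nodes$z[pidx]
    L <- sqrt(dx^2 + dy^2 + dz^2)
    node_path[i] <- node_path[pidx] + L
    if (L <= 0) {
      node_comp[i] <- node_comp[pidx]
      next
    }
    nseg <- max(1L, as.integer(ceiling(L / max_seg_len - 1e-9)))
    r0 <- nodes$radius[pidx]; r1 <- nodes$radius[i]
    seg_len <- L / nseg
    prev_comp <- node_comp[pidx]
    for (ss in seq_len(nseg)) {
      f0 <- (ss - 1) / nseg; f1 <- ss / nseg
      ra0 <- r0 + (r1 - r0) * f0
      ra1 <- r0 + (r1 - r0) * f1
      counter <- counter + 1L
      d_mean <- ra0 + ra1
      area <- pi * (ra0 + ra1) * sqrt(seg_len^2 + (ra1 - ra0)^2)
      # half axial resistance in MOhm: Ra [Ohm cm] = 1e4 Ohm um scale
      r_seg <- 4 * (ra * 1e4) * seg_len / (pi * d_mean^2) / 1e6
      comp[[counter]] <- list(
        index = counter,
        parent = if (is.null(prev_comp) || is.na(prev_comp)) NA_integer_
                 else prev_comp,
        path_pos = node_path[pidx] + (f0 + f1) / 2 * L,
        length = seg_len,
        diameter = d_mean,
        area = area,
        r_half = r_seg / 2,
        label = nodes$label[i]
      )
      prev_comp <- counter
    }
    node_comp[i] <- counter
  }

  if (counter == 0L) {
    # single-node morphology: one spherical compartment
    r <- nodes$radius[1]
    comp[[1]] <- list(index = 1L, parent = NA_integer_, path_pos = 0,
                      length = 2 * r, diameter = 2 * r,
                      area = 4 * pi * r^2, r_half = 0,
                      label = nodes$label[1])
    counter <- 1L
  }

  grid <- dplyr::bind_rows(lapply(comp, tibble::as_tibble))
  grid$branch_id <- 1L
  structure(grid, max_seg_len = max_seg_len, ra = ra,
            class = c("compartment_grid", class(tibble::tibble())))
}

#' Local membrane capacitance of one compartment
#'
#' @param grid A [discretize()] result.
#' @param cm Specific membrane capacitance in uF/cm^2.
#' @param index Compartment index.
#' @return Capacitance in pF (`cm * area`, with 1 um^2 at 1 uF/cm^2 equal
#'   to 0.01 pF).
#' @export
local_capacitance <- function(grid, cm = 1, index) {
  stopifnot(inherits(grid, "compartment_grid"))
  if (any(index < 1 | index > nrow(grid))) {
    abort("compartment index out of range")
  }
  cm * grid$area[index] * 0.01
}

#' Identify boutons on a compartment grid
#'
#' A bouton is a maximal run of compartments whose diameter exceeds
#' `ratio` times the flanking shaft diameter. When the grid carries
#' generator labels the labelled runs are used directly; otherwise the
#' shaft diameter is estimated as a low running quantile of the diameter
#' profile.
#'
#' @param grid A [discretize()] result.
#' @param ratio Diameter ratio defining a bouton (default 1.5).
#' @param window_um Window for the running shaft estimate (default 20).
#' @return `grid` with an added integer `bouton_id` column (`NA` on shaft).
#' @export
find_boutons <- function(grid, ratio = 1.5, window_um = 20) {
  stopifnot(inherits(grid, "compartment_grid"))
  if (any(grid$label %in% c("bouton"))) {
    is_bouton <- grid$label == "bouton"
  } else {
    shaft <- running_quantile(grid$path_pos, grid$diameter, window_um, 0.1)
    is_bouton <- grid$diameter > ratio * shaft
  }
  runs <- rle(is_bouton)
  ids <- rep(NA_integer_, nrow(grid))
  bid <- 0L
  pos <- 1L
  for (k in seq_along(runs$lengths)) {
    len <- runs$lengths[k]
    if (runs$values[k]) {
      bid <- bid + 1L
      ids[pos:(pos + len - 1L)] <- bid
    }
    pos <- pos + len
  }
  grid$bouton_id <- ids
  grid
}

running_quantile <- function(x, y, window, prob) {
  vapply(x, function(xi) {
    sel <- abs(x - xi) <= window / 2
    stats::quantile(y[sel], prob, names = FALSE)
  }, numeric(1))
}

#' Per-bouton geometry summary
#'
#' @param grid A grid with `bouton_id` (see [find_boutons()]).
#' @param cm Specific capacitance in uF/cm^2.
#' @return A tibble with one row per bouton: position, max diameter, total
#'   membrane area, and local capacitance.
#' @export
bouton_summary <- function(grid, cm = 1) {
  stopifnot("bouton_id" %in% names(grid))
  grid %>%
    dplyr::filter(!is.na(.data$bouton_id)) %>%
    dplyr::group_by(.data$bouton_id) %>%
    dplyr::summarise(
      path_pos = mean(.data$path_pos),
      diameter = max(.data$diameter),
      area = sum(.data$area),
      capacitance_pf = cm * sum(.data$area) * 0.01,
      n_comp = dplyr::n(),
      .groups = "drop"
    )
}
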