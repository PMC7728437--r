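#' Construct a SAC morphology from a node table
#'
#' A morphology is a rooted tree of 3-D points with radii, stored as a
#' data frame with one row per node and columns `id`, `parent_id`, `x`,
#' `y`, `z` (micrometres), `radius` (micrometres) and
#' `kind` (`"soma"`, `"dendrite"` or `"varicosity"`).
#' The root (soma) has `parent_id = -1`. Terminal (leaf) nodes represent
#' transmitter-release varicosities and are relabelled
#' `kind = "varicosity"` if needed.
#'
#' @param nodes data frame with the columns listed above; parents must
#'   appear before their children.
#' @param radial_extent planar radius of the arbor in micrometres; computed
#'   from the node table when `NULL`.
#' @param seed,provenance optional metadata stored as attributes.
#' @return an object of class `sac_morphology` (a validated data frame).
#' @export
sac_morphology <- function(nodes, radial_extent = NULL, seed = NA_integer_,
                           provenance = "user") {
  required <- c("id", "parent_id", "x", "y", "z", "radius", "kind")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols)) {
    stop("morphology table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  nodes <- as.data.frame(nodes)[required]
  nodes$id <- as.integer(nodes$id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  validate_morphology_nodes(nodes)
  # leaves are release sites by definition
  is_parent <- nodes$id %in% nodes$parent_id
  leaf <- !is_parent & nodes$parent_id != -1L
  nodes$kind[leaf] <- "varicosity"
  if (is.null(radial_extent)) {
    root <- which(nodes$parent_id == -1L)
    radial_extent <- max(sqrt((nodes$x - nodes$x[root])^2 +
                              (nodes$y - nodes$y[root])^2))
  }
  structure(nodes,
            class = c("sac_morphology", "data.frame"),
            radial_extent = radial_extent,
            seed = seed,
            provenance = provenance)
}

validate_morphology_nodes <- function(nodes, line_of = NULL) {
  fail <- function(msg, i) {
    loc <- if (!is.null(line_of)) sprintf(" (line %d)", line_of[i]) else
      sprintf(" (node id %s)", nodes$id[i])
    stop("invalid morphology: ", msg, loc, call. = FALSE)
  }
  if (anyDuplicated(nodes$id)) {
    fail("duplicate node id", which(duplicated(nodes$id))[1])
  }
  roots <- which(nodes$parent_id == -1L)
  if (length(roots) != 1L) {
    stop("invalid morphology: expected exactly one root, found ",
         length(roots), call. = FALSE)
  }
  if (any(nodes$radius <= 0)) fail("nonpositive radius", which(nodes$radius <= 0)[1])
  # parents must already be defined when a child appears: this both catches
  # dangling references and (with unique ids) rules out cycles
  seen <- logical(0)
  idx <- seq_len(nrow(nodes))
  pos <- match(nodes$parent_id, nodes$id)
  bad <- which(nodes$parent_id != -1L & (is.na(pos) | pos >= idx))
  if (length(bad)) {
    i <- bad[1]
    if (is.na(pos[i])) fail(paste0("parent id ", nodes$parent_id[i], " undefined"), i)
    fail("parent defined after child (cycle or misordered table)", i)
  }
  invisible(nodes)
}

#' Generate a synthetic SAC-like dendritic morphology
#'
#' Builds a planar, radially symmetric starburst arbor: a spherical soma,
#' `n_primary` primary dendrites leaving the soma at evenly spaced angles
#' (plus seeded jitter), binary branching of order `branch_order`, cable
#' diameters tapering from `diam_proximal` at the soma to `diam_distal` at
#' the tips, and bead-like release varicosities along the distal third of
#' the arbor. Starburst dendrites are among the thinnest in the retina
#' (on the order of 0.1 um) and their distal zone is densely beaded; the
#' defaults reflect that anatomy, which is what gives the cell its strong
#' electrotonic soma-to-tip isolation.
#'
#' @param radial_extent planar radius of the arbor, um (80-200).
#' @param n_primary number of primary dendrites (>= 2).
#' @param branch_order number of binary branch points per primary (>= 1);
#'   the arbor has `n_primary * 2^branch_order` terminal varicosities.
#' @param diam_soma soma diameter, um.
#' @param diam_proximal,diam_distal cable diameter at the soma end and the
#'   tips, um; must taper monotonically (soma >= proximal >= distal).
#' @param varicosity_diam diameter of varicosity beads, um.
#' @param varicosity_spacing spacing of en-passant beads along distal
#'   dendrites, um.
#' @param varicosity_zone fraction of `radial_extent` beyond which
#'   dendrites are beaded (the distal release zone).
#' @param seed integer seed; identical arguments and seed give a
#'   byte-identical node table.
#' @return a [sac_morphology] object.
#' @examples
#' m <- generate_sac_morphology(n_primary = 4, branch_order = 3, seed = 1)
#' sum(morphology_terminals(m) > 0)  # 32 terminals
#' @export
generate_sac_morphology <- function(radial_extent = 110, n_primary = 6,
                                    branch_order = 5, diam_soma = 8,
                                    diam_proximal = 0.10, diam_distal = 0.08,
                                    varicosity_diam = 1.5,
                                    varicosity_spacing = 2,
                                    varicosity_zone = 2 / 3,
                                    seed = 1L) {
  if (radial_extent < 80 || radial_extent > 200) {
    stop("radial_extent must lie in [80, 200] um")
  }
  if (n_primary < 2) stop("n_primary must be >= 2")
  if (branch_order < 1) stop("branch_order must be >= 1")
  if (!(diam_soma >= diam_proximal && diam_proximal >= diam_distal &&
        diam_distal > 0)) {
    stop("diameters must taper monotonically soma -> proximal -> distal")
  }
  rng <- local_rng(seed)
  on.exit(rng())

  seg_len <- radial_extent / (branch_order + 1)
  bead_r0 <- varicosity_zone * radial_extent
  taper <- function(r) {
    (diam_proximal + (diam_distal - diam_proximal) *
       pmin(r / radial_extent, 1)) / 2
  }

  n_guess <- n_primary * 2^(branch_order + 2) *
    ceiling(seg_len / min(varicosity_spacing, 5)) + 1L
  ids <- integer(n_guess); parents <- integer(n_guess)
  xs <- numeric(n_guess); ys <- numeric(n_guess); zs <- numeric(n_guess)
  rads <- numeric(n_guess); kinds <- character(n_guess)
  nid <- 1L
  ids[1] <- 1L; parents[1] <- -1L
  xs[1] <- ys[1] <- zs[1] <- 0
  rads[1] <- diam_soma / 2; kinds[1] <- "soma"

  # breadth-first over branches so parents precede children
  queue <- vector("list", n_primary)
  for (i in seq_len(n_primary)) {
    ang <- 2 * pi * (i - 1) / n_primary + stats::rnorm(1, 0, 0.03)
    queue[[i]] <- list(parent = 1L, angle = ang, level = 1L)
  }
  spread <- pi / 2
  while (length(queue)) {
    br <- queue[[1]]; queue <- queue[-1]
    p <- match(br$parent, ids[seq_len(nid)])
    px <- xs[p]; py <- ys[p]
    ang <- br$angle + stats::rnorm(1, 0, 0.02)
    terminal_level <- br$level > branch_order
    r_start <- sqrt(px^2 + py^2)
    sub_len <- if (r_start + seg_len / 2 > bead_r0) varicosity_spacing else 5
    n_sub <- max(1L, ceiling(seg_len / sub_len))
    prev <- br$parent
    for (s in seq_len(n_sub)) {
      nid <- nid + 1L
      frac <- seg_len * s / n_sub
      x <- px + cos(ang) * frac
      y <- py + sin(ang) * frac
      rr <- sqrt(x^2 + y^2)
      beaded <- rr > bead_r0
      is_last <- s == n_sub
      kind <- if ((beaded && !is_last) || (is_last && terminal_level)) {
        "varicosity"
      } else {
        "dendrite"
      }
      ids[nid] <- nid; parents[nid] <- prev
      xs[nid] <- x; ys[nid] <- y
      zs[nid] <- stats::rnorm(1, 0, 0.05)
      rads[nid] <- if (kind == "varicosity") varicosity_diam / 2 else taper(rr)
      kinds[nid] <- kind
      prev <- nid
    }
    if (!terminal_level) {
      da <- spread / 2^br$level
      queue[[length(queue) + 1L]] <- list(parent = prev, angle = ang - da,
                                          level = br$level + 1L)
      queue[[length(queue) + 1L]] <- list(parent = prev, angle = ang + da,
                                          level = br$level + 1L)
    }
  }
  nodes <- data.frame(id = ids[seq_len(nid)], parent_id = parents[seq_len(nid)],
                      x = xs[seq_len(nid)], y = ys[seq_len(nid)],
                      z = zs[seq_len(nid)], radius = rads[seq_len(nid)],
                      kind = kinds[seq_len(nid)], stringsAsFactors = FALSE)
  sac_morphology(nodes, radial_extent = radial_extent, seed = seed,
                 provenance = "generate_sac_morphology")
}

#' Path distance from the root
#'
#' Sum of Euclidean 3-D segment lengths along the tree from the soma to a
#' node. Used to classify membrane as proximal dendrite versus distal
#' varicosity zone.
#'
#' @param m a [sac_morphology].
#' @param node_id node id(s); all nodes when `NULL`.
#' @return named numeric vector of distances in micrometres.
#' @export
path_distance <- function(m, node_id = NULL) {
  pidx <- match(m$parent_id, m$id)
  seg <- sqrt((m$x - m$x[pidx])^2 + (m$y - m$y[pidx])^2 + (m$z - m$z[pidx])^2)
  seg[is.na(seg)] <- 0
  pd <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    pd[i] <- if (m$parent_id[i] == -1L) 0 else pd[pidx[i]] + seg[i]
  }
  names(pd) <- m$id
  if (is.null(node_id)) return(pd)
  out <- pd[match(node_id, m$id)]
  if (anyNA(out)) stop("unknown node id: ",
                       paste(node_id[is.na(out)], collapse = ", "))
  names(out) <- node_id
  out
}

#' Terminal varicosities of a morphology
#'
#' @param m a [sac_morphology].
#' @return integer vector of leaf node ids (all of kind `"varicosity"`).
#' @export
morphology_terminals <- function(m) {
  m$id[!(m$id %in% m$parent_id) & m$parent_id != -1L]
}

#' Read a morphology from SWC text
#'
#' Standard 7-column SWC (`id type x y z radius parent`), whitespace
#' separated, `#` comments allowed. Type codes map 1 -> soma,
#' 7 -> varicosity, anything else -> dendrite; coordinates and radii are
#' micrometres. Malformed rows (undefined or forward parent references,
#' duplicate ids, nonpositive radii) raise a format error naming the
#' offending line.
#'
#' @param con file path, connection, or character vector of SWC lines.
#' @return a [sac_morphology].
#' @export
read_swc <- function(con) {
  lines <- if (is.character(con) && length(con) > 1) con else readLines(con)
  keep <- !grepl("^\\s*(#|$)", lines)
  line_no <- which(keep)
  rows <- strsplit(trimws(lines[keep]), "\\s+")
  if (!length(rows)) stop("SWC input has no data rows")
  bad_len <- which(lengths(rows) != 7L)
  if (length(bad_len)) {
    stop("SWC format error: expected 7 columns (line ",
         line_no[bad_len[1]], ")")
  }
  tab <- matrix(suppressWarnings(as.numeric(unlist(rows))),
                ncol = 7, byrow = TRUE)
  if (anyNA(tab)) {
    stop("SWC format error: non-numeric field (line ",
         line_no[which(rowSums(is.na(tab)) > 0)[1]], ")")
  }
  kind <- c("soma", "dendrite")[ifelse(tab[, 2] == 1, 1, 2)]
  kind[tab[, 2] == 7] <- "varicosity"
  nodes <- data.frame(id = as.integer(tab[, 1]),
                      parent_id = as.integer(tab[, 7]),
                      x = tab[, 3], y = tab[, 4], z = tab[, 5],
                      radius = tab[, 6], kind = kind,
                      stringsAsFactors = FALSE)
  validate_morphology_nodes(nodes, line_of = line_no)
  sac_morphology(nodes, provenance = "swc")
}

#' Write a morphology as SWC text
#'
#' Inverse of [read_swc()]: soma -> type 1, dendrite -> type 3,
#' varicosity -> type 7. Reading the output back recovers the same node
#' set up to numeric formatting.
#'
#' @param m a [sac_morphology].
#' @param con file path or connection; the lines are returned invisibly,
#'   so `con = NULL` can be used to capture them.
#' @export
write_swc <- function(m, con = NULL) {
  type <- c(soma = 1L, dendrite = 3L, varicosity = 7L)[m$kind]
  lines <- sprintf("%d %d %.6g %.6g %.6g %.6g %d",
                   m$id, type, m$x, m$y, m$z, m$radius, m$parent_id)
  lines <- c("# SWC export (um); type 7 = release varicosity", lines)
  if (!is.null(con)) writeLines(lines, con)
  invisible(lines)
}

#' @export
print.sac_morphology <- function(x, ...) {
  term <- morphology_terminals(x)
  cat(sprintf(paste0("SAC morphology: %d nodes, %d terminal varicosities, ",
                     "radial extent %.0f um (%s)\n"),
              nrow(x), length(term), attr(x, "radial_extent"),
              attr(x, "provenance")))
  invisible(x)
}

#' @export
plot.sac_morphology <- function(x, ...) {
  pidx <- match(x$parent_id, x$id)
  ok <- !is.na(pidx)
  graphics::plot(x$x, x$y, type = "n", asp = 1, xlab = "x (um)",
                 ylab = "y (um)", ...)
  graphics::segments(x$x[pidx[ok]], x$y[pidx[ok]], x$x[ok], x$y[ok],
                     col = "grey40")
  v <- x$kind == "varicosity"
  graphics::points(x$x[v], x$y[v], pch = 16, cex = 0.3, col = "firebrick")
  graphics::points(0, 0, pch = 16, cex = 1.2)
  invisible(x)
}

# run code under a private RNG stream, restoring the caller's state
local_rng <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}
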