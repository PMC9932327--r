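# Labeled compartment trees: the spatial substrate of the cable equation.
# A morphology is a data.frame of cylindrical compartments (id, parent_id,
# ctype, length, radius, optional xyz) plus passive membrane constants.

.ctypes <- c("soma", "main", "smooth", "spiny")

#' Construct a compartment-tree morphology
#'
#' Builds and validates a labeled compartment tree. Each compartment is a
#' cylinder with a type label (`soma`, `main`, `smooth`, `spiny`) that
#' determines its ion-channel inventory. The tree must be connected and
#' acyclic, rooted at a single soma compartment.
#'
#' @param compartments data.frame with columns `id` (integer), `parent_id`
#'   (integer, `NA` for the root), `ctype` (one of soma/main/smooth/spiny),
#'   `length` (um), `radius` (um), and optionally `x`, `y`, `z` (um).
#' @param passive list with `c_m` (membrane capacitance, uF/cm^2), `r_axial`
#'   (axial resistivity, Ohm*cm), `e_leak` (leak reversal potential, mV).
#' @return An object of class `pc_morphology`.
#' @export
morphology <- function(compartments,
                       passive = list(c_m = 1.64, r_axial = 250, e_leak = -80.5)) {
  stopifnot(is.data.frame(compartments))
  req <- c("id", "parent_id", "ctype", "length", "radius")
  missing_cols <- setdiff(req, names(compartments))
  if (length(missing_cols) > 0L) {
    stop("morphology: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  cmp <- compartments
  cmp$id <- as.integer(cmp$id)
  cmp$parent_id <- as.integer(cmp$parent_id)
  cmp$ctype <- as.character(cmp$ctype)
  if (anyDuplicated(cmp$id)) stop("morphology: duplicate compartment ids")
  if (!all(cmp$ctype %in% .ctypes)) {
    stop("morphology: unknown ctype(s): ",
         paste(unique(setdiff(cmp$ctype, .ctypes)), collapse = ", "))
  }
  if (any(!is.finite(cmp$length)) || any(cmp$length <= 0)) {
    stop("morphology: all lengths must be positive")
  }
  if (any(!is.finite(cmp$radius)) || any(cmp$radius <= 0)) {
    stop("morphology: all radii must be positive")
  }
  roots <- which(is.na(cmp$parent_id))
  if (length(roots) != 1L) {
    stop("morphology: expected exactly one root, found ", length(roots))
  }
  if (cmp$ctype[roots] != "soma") stop("morphology: root compartment must be soma")
  nonroot <- cmp$parent_id[!is.na(cmp$parent_id)]
  if (!all(nonroot %in% cmp$id)) stop("morphology: parent_id refers to missing compartment")
  m <- structure(list(compartments = cmp, passive = passive),
                 class = "pc_morphology")
  .check_tree(m)
  m
}

# connected + acyclic: every compartment must reach the root by parent links
.check_tree <- function(m) {
  cmp <- m$compartments
  idx <- match(cmp$parent_id, cmp$id)      # NA at root
  n <- nrow(cmp)
  for (i in seq_len(n)) {
    seen <- logical(n)
    j <- i
    while (!is.na(idx[j])) {
      if (seen[j]) stop("morphology: cycle detected involving compartment id ", cmp$id[i])
      seen[j] <- TRUE
      j <- idx[j]
      if (sum(seen) > n) stop("morphology: cycle detected")
    }
  }
  invisible(m)
}

#' @export
print.pc_morphology <- function(x, ...) {
  ct <- count_by_type(x)
  cat("pc_morphology:", nrow(x$compartments), "compartments (",
      paste(sprintf("%s %d", names(ct), ct), collapse = ", "), ")\n")
  cat("passive: c_m", x$passive$c_m, "uF/cm^2, R", x$passive$r_axial,
      "Ohm*cm, E_leak", x$passive$e_leak, "mV\n")
  invisible(x)
}

#' Count compartments by type
#'
#' @param m a `pc_morphology`.
#' @return Named integer vector over `soma`, `main`, `smooth`, `spiny`;
#'   counts always sum to the total compartment count.
#' @export
count_by_type <- function(m) {
  stopifnot(inherits(m, "pc_morphology"))
  tab <- table(factor(m$compartments$ctype, levels = .ctypes))
  setNames(as.integer(tab), .ctypes)
}

#' Read a morphology from an SWC file
#'
#' Standard 7-column SWC (`id type x y z radius parent`), `#` comments.
#' Consecutive points that share the SWC soma type are collapsed into a single
#' root soma compartment. Compartment length is the euclidean distance to the
#' parent point (the root uses twice its radius, a sphere-equivalent cylinder).
#'
#' @param path file path.
#' @param type_map named integer vector mapping SWC integer types to ctypes;
#'   default `c("1" = "soma", "2" = "main", "3" = "spiny", "4" = "main",
#'   "5" = "smooth")`.
#' @param passive passive constants, as in [morphology()].
#' @return A `pc_morphology`.
#' @export
read_swc <- function(path,
                     type_map = c("1" = "soma", "2" = "main", "3" = "spiny",
                                  "4" = "main", "5" = "smooth"),
                     passive = list(c_m = 1.64, r_axial = 250, e_leak = -80.5)) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0L) stop("read_swc: no data lines in ", path)
  parse_line <- function(i) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(toks) != 7L || anyNA(suppressWarnings(as.numeric(toks)))) {
      stop("read_swc: malformed SWC line ", i, ": '", lines[i], "'")
    }
    as.numeric(toks)
  }
  mat <- t(vapply(rows, parse_line, numeric(7)))
  colnames(mat) <- c("id", "type", "x", "y", "z", "radius", "parent")
  df <- as.data.frame(mat)
  if (sum(df$parent == -1) > 1L) stop("read_swc: multiple roots in ", path)
  ctype <- unname(type_map[as.character(as.integer(df$type))])
  if (anyNA(ctype)) {
    stop("read_swc: SWC type(s) without mapping: ",
         paste(unique(df$type[is.na(ctype)]), collapse = ", "))
  }
  # collapse a chain of soma-type points into one root compartment
  soma_rows <- which(ctype == "soma")
  root_row <- which(df$parent == -1)
  if (length(root_row) != 1L) stop("read_swc: no root point (parent -1)")
  collapse <- soma_rows
  keep_rows <- setdiff(seq_len(nrow(df)), setdiff(collapse, root_row))
  pid <- df$parent
  # reparent children of collapsed soma points onto the root point
  pid[pid %in% df$id[collapse]] <- df$id[root_row]
  df2 <- df[keep_rows, ]
  pid2 <- pid[keep_rows]
  parent_xyz <- function(k) {
    p <- pid2[k]
    if (p == -1) return(NULL)
    j <- which(df2$id == p)
    if (length(j) != 1L) stop("read_swc: parent ", p, " not found (cycle or forward reference)")
    as.numeric(df2[j, c("x", "y", "z")])
  }
  len <- vapply(seq_len(nrow(df2)), function(k) {
    pp <- parent_xyz(k)
    if (is.null(pp)) return(2 * df2$radius[k])
    d <- sqrt(sum((as.numeric(df2[k, c("x", "y", "z")]) - pp)^2))
    if (d <= 0) 2 * df2$radius[k] else d
  }, numeric(1))
  cmp <- data.frame(
    id = as.integer(df2$id),
    parent_id = ifelse(pid2 == -1, NA_integer_, as.integer(pid2)),
    ctype = ctype[keep_rows],
    length = len,
    radius = df2$radius,
    x = df2$x, y = df2$y, z = df2$z
  )
  morphology(cmp, passive = passive)
}

#' Write a morphology to an SWC file
#'
#' Inverse of [read_swc()] up to the soma collapse: positions are taken from
#' the stored xyz columns if present, otherwise compartments are laid out
#' along x by cumulative length from the root.
#'
#' @param m a `pc_morphology`.
#' @param path output file path.
#' @param type_map named character vector mapping ctype to SWC integer type;
#'   default inverts the [read_swc()] default.
#' @return `path`, invisibly.
#' @export
write_swc <- function(m, path,
                      type_map = c(soma = 1L, main = 4L, smooth = 5L, spiny = 3L)) {
  cmp <- m$compartments
  if (!all(c("x", "y", "z") %in% names(cmp))) {
    cmp <- .layout_along_x(cmp)
  }
  swc_type <- unname(type_map[cmp$ctype])
  parent <- ifelse(is.na(cmp$parent_id), -1L, cmp$parent_id)
  lines <- sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                   cmp$id, swc_type, cmp$x, cmp$y, cmp$z, cmp$radius, parent)
  writeLines(c("# SWC written by pcseq", lines), path)
  invisible(path)
}

.layout_along_x <- function(cmp) {
  idx <- match(cmp$parent_id, cmp$id)
  x <- numeric(nrow(cmp))
  # parents always resolvable; iterate in topological order
  order_ <- .topo_order(cmp)
  for (i in order_) {
    p <- idx[i]
    x[i] <- if (is.na(p)) 0 else x[p] + cmp$length[i]
  }
  cmp$x <- x; cmp$y <- 0; cmp$z <- 0
  cmp
}

.topo_order <- function(cmp) {
  idx <- match(cmp$parent_id, cmp$id)
  n <- nrow(cmp)
  depth <- integer(n)
  for (i in seq_len(n)) {
    d <- 0L; j <- i
    while (!is.na(idx[j])) { d <- d + 1L; j <- idx[j]; if (d > n) stop("cycle") }
    depth[i] <- d
  }
  order(depth)
}

#' Read a morphology from a GENESIS ".p" file
#'
#' Parses the relative-coordinate dialect used by the original Purkinje-cell
#' compartmental model: lines of the form
#' `name parent x y z diameter` (coordinates um, relative to the parent;
#' `parent` is `none` for the root or `.` for the previous line's
#' compartment). `*`-directives and comments (`//`) are ignored. Compartment
#' length is the norm of the relative offset. Name prefixes are mapped to the
#' four ctypes by `prefix_map` (first match wins).
#'
#' @param path file path.
#' @param prefix_map named character vector: names are compartment-name
#'   prefixes, values the ctype each maps to; the longest matching prefix
#'   wins.
#' @param passive passive constants, as in [morphology()].
#' @return A `pc_morphology`.
#' @export
read_genesis_p <- function(path,
                           prefix_map = c(soma = "soma", main = "main",
                                          md = "main", smooth = "smooth",
                                          sd = "smooth", spiny = "spiny",
                                          br = "spiny", b = "spiny"),
                           passive = list(c_m = 1.64, r_axial = 250, e_leak = -80.5)) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("//.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "*")]
  name <- character(0); parent <- character(0)
  dx <- dy <- dz <- diam <- numeric(0)
  prev <- NA_character_
  for (i in seq_along(lines)) {
    toks <- strsplit(lines[i], "\\s+")[[1]]
    if (length(toks) < 6L) stop("read_genesis_p: malformed line: '", lines[i], "'")
    nm <- toks[1]
    pa <- toks[2]
    if (pa == ".") {
      if (is.na(prev)) stop("read_genesis_p: '.' parent with no previous compartment")
      pa <- prev
    }
    vals <- suppressWarnings(as.numeric(toks[3:6]))
    if (anyNA(vals)) stop("read_genesis_p: non-numeric geometry: '", lines[i], "'")
    name <- c(name, nm); parent <- c(parent, pa)
    dx <- c(dx, vals[1]); dy <- c(dy, vals[2]); dz <- c(dz, vals[3])
    diam <- c(diam, vals[4])
    prev <- nm
  }
  ctype <- vapply(name, function(nm) {
    match_ <- vapply(names(prefix_map), function(p) startsWith(nm, p), logical(1))
    if (!any(match_)) stop("read_genesis_p: no ctype mapping for name '", nm, "'")
    hits <- prefix_map[match_]
    unname(hits[which.max(nchar(names(hits)))])
  }, character(1))
  id <- seq_along(name)
  parent_id <- ifelse(parent == "none", NA_integer_, match(parent, name))
  bad <- which(parent != "none" & is.na(parent_id))
  if (length(bad) > 0L) {
    stop("read_genesis_p: unknown parent compartment '", parent[bad[1]], "'")
  }
  fwd <- which(!is.na(parent_id) & parent_id >= id)
  if (length(fwd) > 0L) {
    stop("read_genesis_p: compartment '", name[fwd[1]],
         "' declared before its parent '", parent[fwd[1]], "'")
  }
  len <- sqrt(dx^2 + dy^2 + dz^2)
  len[len <= 0] <- diam[len <= 0]       # point soma: sphere-equivalent cylinder
  cmp <- data.frame(id = id, parent_id = parent_id, ctype = unname(ctype),
                    length = len, radius = diam / 2)
  morphology(cmp, passive = passive)
}

#' Generate a reduced synthetic morphology
#'
#' Builds a deterministic, reduced Purkinje-like tree for tests and
#' desk-scale experiments: a soma root, then `n_main` main-dendrite
#' compartments in a chain, then `n_smooth` smooth compartments, then
#' `n_spiny` spiny compartments, layered root-to-tip. With `branching > 1`
#' the smooth and spiny layers branch (each non-terminal compartment gets up
#' to `branching` children), with child radii attenuated so paths taper
#' toward the tips; `branching = 1` gives a linear chain.
#'
#' Geometry defaults (soma 10 um radius; main 3, smooth 1.25, spiny 0.7 um;
#' lengths 20-40 um, thicker types longer, as in compartmental
#' reconstructions) keep the passive length constant long relative to a
#' single compartment, so charge spreads across several compartments rather
#' than equilibrating instantly, and keep the explicit diffusion stability
#' bound above the default time step.
#'
#' @param n_main,n_smooth,n_spiny compartment counts per layer (>= 0).
#' @param branching maximum children per smooth/spiny compartment (>= 1).
#' @param seed integer seed; generation is bit-reproducible for a fixed seed.
#' @param lengths,radii named lists (um) overriding per-type geometry.
#' @param passive passive constants, as in [morphology()].
#' @return A `pc_morphology`.
#' @export
generate_reduced <- function(n_main = 4, n_smooth = 8, n_spiny = 30,
                             branching = 2, seed = 1L,
                             lengths = list(soma = 20, main = 40, smooth = 30, spiny = 20),
                             radii = list(soma = 10, main = 3, smooth = 1.25, spiny = 0.7),
                             passive = list(c_m = 1.64, r_axial = 250, e_leak = -80.5)) {
  if (n_main < 0 || n_smooth < 0 || n_spiny < 0) stop("generate_reduced: counts must be >= 0")
  if (branching < 1) stop("generate_reduced: branching must be >= 1")
  total <- 1L + n_main + n_smooth + n_spiny
  if (total < 2L) stop("generate_reduced: morphology needs at least 2 compartments")
  rng <- .lcg_new(seed)

  id <- 1L
  rows <- list(data.frame(id = 1L, parent_id = NA_integer_, ctype = "soma",
                          length = lengths$soma, radius = radii$soma))
  frontier <- 1L                       # attachment points for the next layer
  # breadth-first growth: open slots form a FIFO so the layer fills level by
  # level; each parent accepts at most `branch` children
  add_layer <- function(n, ct, rows, frontier, branch) {
    if (n == 0L) return(list(rows = rows, frontier = frontier))
    q_id <- frontier
    q_cap <- rep(as.integer(branch), length(frontier))
    added <- integer(0)
    for (k in seq_len(n)) {
      id <<- id + 1L
      parent <- q_id[1]
      depth_jitter <- 1 + 0.1 * (.lcg_next(rng) - 0.5)   # mild length variety
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, parent_id = parent, ctype = ct,
        length = lengths[[ct]] * depth_jitter, radius = radii[[ct]])
      q_cap[1] <- q_cap[1] - 1L
      if (q_cap[1] <= 0L) { q_id <- q_id[-1]; q_cap <- q_cap[-1] }
      q_id <- c(q_id, id); q_cap <- c(q_cap, as.integer(branch))
      added <- c(added, id)
    }
    parents_used <- vapply(rows, function(r) r$parent_id, integer(1))
    list(rows = rows, frontier = setdiff(added, parents_used))
  }
  lay <- add_layer(n_main, "main", rows, frontier, 1L)      # main is a chain
  lay <- add_layer(n_smooth, "smooth", lay$rows, lay$frontier, branching)
  lay <- add_layer(n_spiny, "spiny", lay$rows, lay$frontier, branching)
  cmp <- do.call(rbind, lay$rows)
  morphology(cmp, passive = passive)
}

# Minimal deterministic LCG so generation never touches R's global RNG.
.lcg_new <- function(seed) {
  e <- new.env()
  e$state <- (as.numeric(seed) %% 2147483647) + 1
  e
}
.lcg_next <- function(rng) {
  rng$state <- (rng$state * 48271) %% 2147483647
  rng$state / 2147483647
}

#' Extract a straight stimulation path
#'
#' Returns `n` distinct compartments forming a simple path that starts at
#' `start_id` and walks either toward the soma (parent links) or away from it
#' (descending children, taking the largest-radius child at a branch, lowest
#' id on ties). The soma itself is never included.
#'
#' @param m a `pc_morphology`.
#' @param start_id starting compartment id.
#' @param n path length (>= 1).
#' @param toward_soma logical; walk direction.
#' @return Integer vector of `n` compartment ids, in walk order.
#' @export
straight_path <- function(m, start_id, n, toward_soma = TRUE) {
  stopifnot(inherits(m, "pc_morphology"), n >= 1)
  cmp <- m$compartments
  if (!start_id %in% cmp$id) stop("straight_path: start_id ", start_id, " not in morphology")
  soma_id <- cmp$id[is.na(cmp$parent_id)]
  if (start_id == soma_id) stop("straight_path: path may not include the soma")
  path <- integer(0)
  cur <- start_id
  while (length(path) < n) {
    if (is.na(cur) || cur == soma_id) break
    path <- c(path, cur)
    if (length(path) == n) break
    if (toward_soma) {
      cur <- cmp$parent_id[match(cur, cmp$id)]
    } else {
      kids <- cmp[which(cmp$parent_id == cur), , drop = FALSE]
      if (nrow(kids) == 0L) { cur <- NA_integer_ } else {
        kids <- kids[order(-kids$radius, kids$id), , drop = FALSE]
        cur <- kids$id[1]
      }
    }
  }
  if (length(path) < n) {
    stop("straight_path: only ", length(path), " compartments available (requested ", n, ")")
  }
  path
}

#' Serialize / deserialize a morphology as JSON
#'
#' Fixture-friendly plain-text round trip of the full tree and passive block.
#'
#' @param m a `pc_morphology`.
#' @param path file path.
#' @return `read_morphology_json` returns a `pc_morphology`;
#'   `write_morphology_json` returns `path` invisibly.
#' @export
write_morphology_json <- function(m, path) {
  jsonlite::write_json(list(compartments = m$compartments, passive = m$passive),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_morphology_json
#' @export
read_morphology_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cmp <- as.data.frame(obj$compartments)
  cmp$parent_id <- vapply(cmp$parent_id, function(p)
    if (is.null(p) || is.na(p)) NA_integer_ else as.integer(p), integer(1))
  morphology(cmp, passive = obj$passive)
}
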