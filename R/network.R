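#' Vascular network data model
#'
#' A `vessel_network` is a directed, strictly bifurcating tree of straight
#' cylindrical vessel segments rooted at the main pulmonary artery (MPA).
#' Each segment carries a length `L` (cm), a reference radius `r0` (cm, the
#' radius at diastolic pressure so that the diastolic area is `pi * r0^2`),
#' an extralobar flag (MPA/LPA/RPA), and an optional wall stiffness `Eh/r0`
#' (dyn/cm2). Internally the network is stored as a data frame of segments
#' plus the root id.
#'
#' @param segments data frame with columns `id` (integer), `name` (character),
#'   `parent` (integer, `NA` for the root), `length` (cm), `r0` (cm),
#'   `extralobar` (logical) and optionally `stiffness` (dyn/cm2, `NA` until
#'   assigned).
#' @param root_id id of the root (MPA) segment. Defaults to the unique
#'   segment with no parent.
#' @param validate if `TRUE` (default) invariants are checked and violations
#'   raise an error.
#' @return An object of class `vessel_network`.
#' @export
vessel_network <- function(segments, root_id = NULL, validate = TRUE) {
  required <- c("id", "name", "parent", "length", "r0", "extralobar")
  missing_cols <- setdiff(required, names(segments))
  if (length(missing_cols) > 0L) {
    stop("segments is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  if (is.null(segments$stiffness)) segments$stiffness <- NA_real_
  segments$stiffness <- as.numeric(segments$stiffness)
  segments$id <- as.integer(segments$id)
  segments$parent <- as.integer(segments$parent)
  segments$extralobar <- as.logical(segments$extralobar)
  segments <- segments[order(segments$id),
                       c("id", "name", "parent", "length", "r0",
                         "extralobar", "stiffness")]
  rownames(segments) <- NULL
  if (is.null(root_id)) {
    root_id <- segments$id[is.na(segments$parent)]
    if (length(root_id) != 1L) {
      stop("network must have exactly one root (segment with no parent), found ",
           length(root_id))
    }
  }
  net <- structure(list(segments = segments, root_id = as.integer(root_id)),
                   class = "vessel_network")
  if (validate) {
    bad <- validate_network(net)
    if (length(bad) > 0L) {
      stop("invalid network:\n  - ", paste(bad, collapse = "\n  - "))
    }
  }
  net
}

#' @export
print.vessel_network <- function(x, ...) {
  s <- x$segments
  cat(sprintf("<vessel_network> %d segments (%d terminal, %d extralobar), root id %d\n",
              nrow(s), length(terminal_segments(x)), sum(s$extralobar), x$root_id))
  invisible(x)
}

children_of <- function(net, id) {
  net$segments$id[!is.na(net$segments$parent) & net$segments$parent == id]
}

#' Validate a vessel network
#'
#' Checks the structural invariants: one root, bifurcation-only branching
#' (every non-terminal segment has exactly two children), connectivity and
#' acyclicity from the root, strictly positive lengths and radii, resolvable
#' parent references, and an extralobar crown that is connected and contains
#' the root.
#'
#' @param net a `vessel_network` (possibly built with `validate = FALSE`).
#' @return Character vector of human-readable violations; empty if valid.
#' @export
validate_network <- function(net) {
  s <- net$segments
  out <- character(0)
  if (anyDuplicated(s$id)) out <- c(out, "duplicate segment ids")
  roots <- s$id[is.na(s$parent)]
  if (length(roots) != 1L) {
    out <- c(out, sprintf("expected exactly one root, found %d", length(roots)))
  } else if (roots != net$root_id) {
    out <- c(out, sprintf("root_id %d is not the parentless segment %d",
                          net$root_id, roots))
  }
  bad_parent <- !is.na(s$parent) & !(s$parent %in% s$id)
  if (any(bad_parent)) {
    out <- c(out, sprintf("segment %d references unknown parent %d",
                          s$id[bad_parent], s$parent[bad_parent]))
  }
  nonpos_len <- s$id[!(s$length > 0)]
  if (length(nonpos_len) > 0L) {
    out <- c(out, sprintf("nonpositive length in segment %d", nonpos_len))
  }
  nonpos_r <- s$id[!(s$r0 > 0)]
  if (length(nonpos_r) > 0L) {
    out <- c(out, sprintf("nonpositive radius in segment %d", nonpos_r))
  }
  n_children <- vapply(s$id, function(id) length(children_of(net, id)), integer(1))
  bad_deg <- s$id[!(n_children %in% c(0L, 2L))]
  if (length(bad_deg) > 0L) {
    out <- c(out, sprintf("segment %d has %d children (must be 0 or 2)",
                          bad_deg, n_children[match(bad_deg, s$id)]))
  }
  # reachability from root (also catches cycles: unreachable subgraphs)
  if (net$root_id %in% s$id) {
    seen <- integer(0)
    frontier <- net$root_id
    while (length(frontier) > 0L) {
      seen <- c(seen, frontier)
      frontier <- s$id[!is.na(s$parent) & s$parent %in% frontier & !(s$id %in% seen)]
    }
    unreach <- setdiff(s$id, seen)
    if (length(unreach) > 0L) {
      out <- c(out, sprintf("segment %d unreachable from root", unreach))
    }
  }
  # extralobar crown: connected, contains the root
  if (any(s$extralobar)) {
    if (net$root_id %in% s$id && !s$extralobar[s$id == net$root_id]) {
      out <- c(out, "root segment is not flagged extralobar")
    }
    ex <- s[s$extralobar, , drop = FALSE]
    orphan <- ex$id[!is.na(ex$parent) &
                      !(ex$parent %in% s$id[s$extralobar])]
    if (length(orphan) > 0L) {
      out <- c(out, sprintf("extralobar segment %d has non-extralobar parent", orphan))
    }
  }
  out
}

#' Read / write a vessel network
#'
#' The package dialect is a JSON document with a `units` header and a
#' `segments` array (`id`, `name`, `parent`, `length_cm`, `radius_cm`,
#' `extralobar`, optional `stiffness_dyn_cm2`). A CSV edge list with header
#' `id,name,parent,length_cm,radius_cm,extralobar` is accepted as an
#' alternate dialect (chosen by file extension).
#'
#' @param path path to a `.json` or `.csv` file.
#' @param net a `vessel_network`.
#' @return `load_network` returns a validated `vessel_network`;
#'   `save_network` returns `path` invisibly.
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    req <- c("id", "name", "parent", "length_cm", "radius_cm", "extralobar")
    miss <- setdiff(req, names(df))
    if (length(miss) > 0L) {
      stop("malformed network CSV, missing column(s): ",
           paste(miss, collapse = ", "))
    }
    segs <- data.frame(id = df$id, name = df$name, parent = df$parent,
                       length = df$length_cm, r0 = df$radius_cm,
                       extralobar = df$extralobar,
                       stringsAsFactors = FALSE)
    if (!is.null(df$stiffness_dyn_cm2)) segs$stiffness <- df$stiffness_dyn_cm2
  } else {
    doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (is.null(doc$segments)) stop("malformed network JSON: no 'segments' field")
    df <- doc$segments
    req <- c("id", "length_cm", "radius_cm")
    miss <- setdiff(req, names(df))
    if (length(miss) > 0L) {
      stop("malformed network JSON, segment record missing field(s): ",
           paste(miss, collapse = ", "))
    }
    segs <- data.frame(id = df$id,
                       name = if (is.null(df$name)) NA_character_ else df$name,
                       parent = if (is.null(df$parent)) NA_integer_ else df$parent,
                       length = df$length_cm, r0 = df$radius_cm,
                       extralobar = if (is.null(df$extralobar)) FALSE else df$extralobar,
                       stringsAsFactors = FALSE)
    if (!is.null(df$stiffness_dyn_cm2)) segs$stiffness <- df$stiffness_dyn_cm2
  }
  vessel_network(segs)
}

#' @rdname load_network
#' @export
save_network <- function(net, path) {
  s <- net$segments
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- data.frame(id = s$id, name = s$name, parent = s$parent,
                     length_cm = s$length, radius_cm = s$r0,
                     extralobar = s$extralobar,
                     stiffness_dyn_cm2 = s$stiffness)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    doc <- list(
      format = "pulsetree-network",
      units = list(length = "cm", radius = "cm", stiffness = "dyn/cm2"),
      root_id = net$root_id,
      segments = data.frame(id = s$id, name = s$name, parent = s$parent,
                            length_cm = s$length, radius_cm = s$r0,
                            extralobar = s$extralobar,
                            stiffness_dyn_cm2 = s$stiffness)
    )
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Rescale extralobar vessels to measured diastolic areas
#'
#' Replaces the reference radius of the named extralobar vessels so their
#' diastolic area `pi * r0^2` matches the (e.g. MRI-derived) measurement;
#' intralobar radii are left untouched.
#'
#' @param net a `vessel_network`.
#' @param measured_diastolic_areas named numeric vector or list,
#'   names a subset of the extralobar vessel names (MPA/LPA/RPA), values in cm2.
#' @return The rescaled network.
#' @export
scale_extralobar_areas <- function(net, measured_diastolic_areas) {
  areas <- unlist(measured_diastolic_areas)
  if (length(areas) == 0L) return(net)
  s <- net$segments
  known <- s$name[s$extralobar]
  unknown <- setdiff(names(areas), known)
  if (length(unknown) > 0L) {
    stop("unknown extralobar vessel name(s): ", paste(unknown, collapse = ", "))
  }
  if (any(!(areas > 0))) stop("measured diastolic areas must be positive")
  for (nm in names(areas)) {
    s$r0[s$name == nm] <- sqrt(areas[[nm]] / pi)
  }
  net$segments <- s
  net
}

#' Poiseuille resistance of a segment
#'
#' `8 * mu * L / (pi * r0^4)` for fully developed laminar flow, used to
#' distribute the total pulmonary vascular resistance over terminal outlets.
#'
#' @param segment one-row data frame (or list) with `length` and `r0` in cm.
#' @param mu dynamic viscosity in dyn*s/cm2 (Poise); default 0.03.
#' @return Resistance in dyn*s/cm5.
#' @export
poiseuille_resistance <- function(segment, mu = 0.03) {
  stopifnot(mu > 0)
  8 * mu * segment$length / (pi * segment$r0^4)
}

#' Terminal segments of a network
#'
#' @param net a `vessel_network`.
#' @return Integer vector of ids of childless segments, sorted by id (the
#'   deterministic ordering used for all parameter vectors).
#' @export
terminal_segments <- function(net) {
  s <- net$segments
  sort(setdiff(s$id, s$parent[!is.na(s$parent)]))
}

#' Root-to-terminal cumulative Poiseuille resistance
#'
#' Sums `8 mu L / (pi r0^4)` along the unique path from the root to each
#' terminal segment; this path resistance is the distribution key for
#' nominal Windkessel construction.
#'
#' @inheritParams terminal_segments
#' @param mu dynamic viscosity (Poise).
#' @return Named numeric vector (names = terminal ids) in dyn*s/cm5.
#' @export
path_resistances <- function(net, mu = 0.03) {
  s <- net$segments
  terms <- terminal_segments(net)
  seg_res <- stats::setNames(8 * mu * s$length / (pi * s$r0^4), s$id)
  out <- vapply(terms, function(id) {
    r <- 0
    while (!is.na(id)) {
      r <- r + seg_res[[as.character(id)]]
      id <- s$parent[s$id == id]
    }
    r
  }, numeric(1))
  stats::setNames(out, terms)
}
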