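# OpenDX scalar-field I/O for affinity maps. Values are stored z-fastest
# (the OpenDX standard); the in-memory array is indexed [ix, iy, iz].

#' Write an affinity map in OpenDX format
#'
#' The written origin is `center - spacing * (n - 1)/2` on each axis and the
#' data stream is ordered with the z index varying fastest.
#'
#' @param map an AffinityMap.
#' @param path output path (conventionally `.dx`).
#' @return `path`, invisibly.
#' @export
write_dx <- function(map, path) {
  stopifnot(inherits(map, "AffinityMap"))
  g <- map$grid
  n <- g$npoints
  o <- grid_origin(g)
  vals <- as.vector(aperm(map$energies, c(3, 2, 1)))  # z fastest
  ntot <- length(vals)
  pad <- (3 - ntot %% 3) %% 3
  body <- matrix(c(vals, rep(NA_real_, pad)), ncol = 3, byrow = TRUE)
  data_lines <- apply(body, 1, function(r)
    paste(sprintf("%.6e", r[!is.na(r)]), collapse = " "))
  header <- c(
    sprintf("# OpenDX scalar field: %s probe affinity map", map$probe_name),
    sprintf("object 1 class gridpositions counts %d %d %d", n[1], n[2], n[3]),
    sprintf("origin %.6f %.6f %.6f", o[1], o[2], o[3]),
    sprintf("delta %.6f 0.000000 0.000000", g$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", g$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", g$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            n[1], n[2], n[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            ntot))
  footer <- c("attribute \"dep\" string \"positions\"",
              "object \"regular positions regular connections\" class field",
              "component \"positions\" value 1",
              "component \"connections\" value 2",
              "component \"data\" value 3")
  writeLines(c(header, data_lines, footer), path)
  invisible(path)
}

#' Read an OpenDX scalar field as an affinity map
#'
#' Accepts regular axis-aligned grids with equal spacing on all axes. The
#' probe name is taken from `probe_name` (files written by [write_dx()] do not
#' record it machine-readably).
#'
#' @param path path to a `.dx` file.
#' @param probe_name name to record on the returned map.
#' @param emax_cap cap recorded on the returned map (defaults to the data
#'   maximum).
#' @return an AffinityMap.
#' @export
read_dx <- function(path, probe_name = "unknown", emax_cap = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  cnt_i <- grep("class gridpositions counts", lines)
  if (!length(cnt_i)) stop("malformed DX: no gridpositions object")
  n <- as.integer(strsplit(trimws(sub(".*counts", "", lines[cnt_i[1]])),
                           "\\s+")[[1]])
  if (length(n) != 3 || anyNA(n)) stop("malformed DX: bad counts")
  org_i <- grep("^\\s*origin", lines)[1]
  if (is.na(org_i)) stop("malformed DX: no origin")
  origin <- as.numeric(strsplit(trimws(sub("origin", "", lines[org_i])),
                                "\\s+")[[1]])
  del_i <- grep("^\\s*delta", lines)
  if (length(del_i) < 3) stop("malformed DX: expected 3 delta lines")
  deltas <- t(vapply(lines[del_i[1:3]], function(l)
    as.numeric(strsplit(trimws(sub("delta", "", l)), "\\s+")[[1]]),
    numeric(3)))
  sp <- diag(deltas)
  if (any(abs(deltas - diag(sp)) > 1e-9))
    stop("malformed DX: non-axis-aligned deltas are not supported")
  if (max(abs(sp - sp[1])) > 1e-9)
    stop("malformed DX: anisotropic spacing is not supported")
  arr_i <- grep("class array .*data follows", lines)
  if (!length(arr_i)) stop("malformed DX: no data array object")
  items <- as.integer(sub(".*items\\s+(\\d+)\\s+data follows.*", "\\1",
                          lines[arr_i[1]]))
  if (is.na(items) || items != prod(n))
    stop("malformed DX: item count does not match grid counts")
  vals <- numeric(0)
  i <- arr_i[1] + 1L
  while (length(vals) < items && i <= length(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(tok))
    if (anyNA(v)) break
    vals <- c(vals, v)
    i <- i + 1L
  }
  if (length(vals) != items) stop("malformed DX: truncated data section")
  energies <- aperm(array(vals, dim = rev(n)), c(3, 2, 1))
  center <- origin + sp[1] * (n - 1) / 2
  g <- grid_spec(center = center, npoints = n, spacing = sp[1])
  structure(list(grid = g, probe_name = probe_name, energies = energies,
                 emax_cap = if (is.null(emax_cap)) max(vals) else emax_cap),
            class = "AffinityMap")
}
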