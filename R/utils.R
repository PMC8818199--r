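# internal helpers shared across the package

#' Multiplex assay map
#'
#' The fixed three-multiplex qMSP design: each multiplex amplifies three
#' methylation targets alongside the reference gene ACTB.
#'
#' @return Named list with elements `A`, `B`, `C`, each a character vector of
#'   the marker names carried by that multiplex (ACTB implicit in all three).
#' @examples
#' qmspMultiplexMap()
#' @export
qmspMultiplexMap <- function() {
  list(
    A = c("FAM19A4", "PHACTR3", "PRDM14"),
    B = c("GHSR", "SST", "ZIC1"),
    C = c("MAL", "miR-129", "miR-935")
  )
}

#' Marker names of the nine-target assay
#'
#' @return Character vector of the nine methylation marker names, in
#'   multiplex order.
#' @export
qmspMarkers <- function() {
  unname(unlist(qmspMultiplexMap()))
}

# multiplex carrying a given marker
.multiplexOf <- function(marker) {
  map <- qmspMultiplexMap()
  idx <- vapply(map, function(m) marker %in% m, logical(1))
  if (!any(idx)) stop("unknown marker: ", marker)
  names(map)[idx][1]
}

# coerce case/control labels to logical (TRUE = case)
.asCase <- function(labels) {
  if (is.logical(labels)) return(labels)
  x <- as.character(labels)
  ok <- x %in% c("case", "control") | is.na(x)
  if (!all(ok)) {
    stop("labels must be logical or use the values 'case'/'control'")
  }
  x == "case"
}

# round-half-up for display, mirroring clinical-table conventions
.roundHalfUp <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

# largest-remainder apportionment of n seats to proportions p
.quotaCounts <- function(n, p) {
  if (abs(sum(p) - 1) > 1e-8) stop("composition frequencies must sum to 1")
  q <- n * p
  counts <- floor(q)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(q - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  stats::setNames(as.integer(counts), names(p))
}

# run expr with a locally seeded RNG, restoring global state afterwards
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
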