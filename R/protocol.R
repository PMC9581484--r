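#' Tractography protocol: seed / target / exclusion / stop masks plus rules
#'
#' A protocol bundles the binary masks that constrain one tract
#' reconstruction: a seed (streamline starting points), one or more
#' targets/waypoints (a streamline must pass through every one to be
#' valid), an optional exclusion mask (any visit discards the streamline)
#' and an optional stop mask (truncates propagation).  All masks must live
#' on one grid: registration between spaces is out of scope, so grid
#' identity is enforced instead.
#'
#' @param name full tract name.
#' @param abbreviation short tract code.
#' @param seed binary [volume_grid]; must be nonempty.
#' @param targets list of binary [volume_grid] waypoints (may be empty).
#' @param exclusion optional binary [volume_grid].
#' @param stop optional binary [volume_grid].
#' @param bilateral logical; does this protocol have a mirrored counterpart?
#' @param reverse_seeding logical; run the protocol a second time with seed
#'   and target roles exchanged and sum the two normalized distributions.
#' @return an object of class `tract_protocol`.
#' @export
tract_protocol <- function(name, abbreviation = name, seed, targets = list(),
                           exclusion = NULL, stop = NULL,
                           bilateral = FALSE, reverse_seeding = FALSE) {
  assert_that(inherits(seed, "volume_grid"), "seed must be a volume_grid",
              class = "bxs_protocol_error")
  assert_that(mask_count(seed) > 0, "protocol '%s': seed mask is empty", name,
              class = "bxs_protocol_error")
  for (m in c(targets, list(exclusion, stop))) {
    if (!is.null(m)) assert_same_grid(seed, m, sprintf("protocol '%s' masks", name))
  }
  structure(list(name = name, abbreviation = abbreviation, seed = seed,
                 targets = targets, exclusion = exclusion, stop = stop,
                 bilateral = isTRUE(bilateral),
                 reverse_seeding = isTRUE(reverse_seeding)),
            class = "tract_protocol")
}

#' @export
print.tract_protocol <- function(x, ...) {
  cat(sprintf("<tract_protocol> %s (%s): seed %d vox, %d waypoint(s)%s%s\n",
              x$name, x$abbreviation, mask_count(x$seed), length(x$targets),
              if (!is.null(x$exclusion)) ", exclusion" else "",
              if (x$reverse_seeding) ", reverse-seeded" else ""))
  invisible(x)
}

#' Check the equal-hemisphere-volume rule for a bilateral protocol pair
#'
#' For bilateral protocols the left and right seed masks must have equal
#' voxel counts, and likewise each corresponding target pair, so that the
#' two hemispheres are seeded symmetrically.
#'
#' @param left,right the two [tract_protocol] halves.
#' @return `TRUE` invisibly; error on violation.
#' @export
validate_bilateral <- function(left, right) {
  nl <- mask_count(left$seed); nr <- mask_count(right$seed)
  assert_that(nl == nr,
              paste0("bilateral protocol '%s': seed volumes differ between ",
                     "hemispheres (%d vs %d voxels); seed and target masks ",
                     "must have equal volumes in each hemisphere"),
              left$name, nl, nr, class = "bxs_protocol_error")
  assert_that(length(left$targets) == length(right$targets),
              "bilateral protocol '%s': target count differs", left$name,
              class = "bxs_protocol_error")
  for (i in seq_along(left$targets)) {
    tl <- mask_count(left$targets[[i]]); tr <- mask_count(right$targets[[i]])
    assert_that(tl == tr,
                paste0("bilateral protocol '%s': target %d volumes differ ",
                       "(%d vs %d); equal hemisphere volumes are required"),
                left$name, i, tl, tr, class = "bxs_protocol_error")
  }
  invisible(TRUE)
}

#' Load one protocol from a JSON manifest
#'
#' The manifest names the mask files (relative to its own directory) and
#' the protocol flags:
#' \preformatted{
#' {"name": "...", "abbreviation": "...", "seed": "seed.nii.gz",
#'  "targets": ["t1.nii.gz"], "exclusion": "exc.nii.gz", "stop": null,
#'  "bilateral": false, "reverse_seeding": false, "space": "phantom"}
#' }
#' The free-text `space` tag is carried through but has no semantics.
#'
#' @param descriptor_path path to the JSON manifest.
#' @return a [tract_protocol].
#' @export
load_protocol <- function(descriptor_path) {
  assert_that(file.exists(descriptor_path), "no such protocol manifest: %s",
              descriptor_path, class = "bxs_protocol_error")
  d <- jsonlite::read_json(descriptor_path, simplifyVector = TRUE)
  base <- dirname(descriptor_path)
  assert_that(!is.null(d$seed), "protocol manifest %s has no seed mask",
              descriptor_path, class = "bxs_protocol_error")
  rd <- function(f) read_volume(file.path(base, f))
  targets <- lapply(as.character(d$targets %||% character()), rd)
  p <- tract_protocol(
    name = d$name %||% basename(descriptor_path),
    abbreviation = d$abbreviation %||% d$name,
    seed = rd(d$seed), targets = targets,
    exclusion = if (!is.null(d$exclusion)) rd(d$exclusion),
    stop = if (!is.null(d$stop)) rd(d$stop),
    bilateral = isTRUE(d$bilateral),
    reverse_seeding = isTRUE(d$reverse_seeding))
  p$space <- d$space %||% NA_character_
  p
}

#' Tract library: an ordered set of protocols with categories
#'
#' @param entries list of [tract_protocol] objects.
#' @param categories character vector (association / commissural / limbic /
#'   projection), one per entry.
#' @export
tract_library <- function(entries, categories) {
  assert_that(length(entries) == length(categories),
              "one category per library entry required")
  structure(list(entries = entries, categories = categories),
            class = "tract_library")
}

#' Load a protocol library from a directory
#'
#' Expects `library.json`: an ordered array of
#' `{"protocol": "<subdir-or-file>", "category": "<category>"}` entries.
#'
#' @param dir library directory.
#' @return a [tract_library].
#' @export
load_library <- function(dir) {
  man <- file.path(dir, "library.json")
  assert_that(file.exists(man), "no library.json in %s", dir,
              class = "bxs_protocol_error")
  d <- jsonlite::read_json(man, simplifyVector = FALSE)
  entries <- lapply(d, function(e) {
    p <- file.path(dir, e$protocol)
    if (dir.exists(p)) p <- file.path(p, "protocol.json")
    load_protocol(p)
  })
  tract_library(entries, vapply(d, function(e) e$category, ""))
}

#' Packaged tract-library metadata
#'
#' Returns the shipped table of the 42-tract cross-species protocol
#' library: category, tract name, abbreviation, bilateral flag and
#' reverse-seeding rule for each named bundle.  Bilateral rows expand to a
#' left and a right protocol; commissural rows are single midline
#' protocols.
#'
#' @return a data.frame with columns `category`, `name`, `abbreviation`,
#'   `bilateral`, `reverse_seeding`.
#' @export
tract_library_metadata <- function() {
  path <- system.file("extdata", "tract_library.tsv", package = "bxs")
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  tab$bilateral <- tab$bilateral == "yes"
  tab
}

#' Expanded protocol count of a library metadata table
#'
#' Each bilateral entry contributes a left and a right protocol; each
#' non-bilateral (commissural/midline) entry contributes one.
#'
#' @param meta a data.frame as returned by [tract_library_metadata()].
#' @return integer protocol count after expansion.
#' @export
expanded_protocol_count <- function(meta = tract_library_metadata()) {
  2L * sum(meta$bilateral) + sum(!meta$bilateral)
}
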