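#' Default morphological parameters of the thin myelinated axon
#'
#' Geometry of a 1 um (outer diameter) myelinated brain axon: 21 nodes of
#' Ranvier separated by 20 internode parts, each internode part made of two
#' mirror-image halves of paranodal junction (PNJ), juxtaparanode (JXP) and
#' half-internode (IND) sections under a 15-lamella myelin sheath.  Node
#' centre-to-centre spacing is 100 um, giving a total axon length of ~2 mm.
#'
#' All lengths and diameters are in micrometres; peri-axonal space widths are
#' in nanometres.
#'
#' @return Named list of geometric defaults.
#' @export
morphology_defaults <- function() {
  list(
    n_internodes        = 20L,
    axon_outer_diam_um  = 1,     # outer diameter of the myelin sheath
    node_length_um      = 1,
    node_diam_um        = 0.7,
    pnj_length_um       = 3,
    pnj_diam_um         = 0.7,
    jxp_length_um       = 5,
    jxp_diam_um         = 0.8,
    ind_length_um       = 83,
    ind_diam_um         = 0.8,
    pnj_periax_width_nm = 1.8,
    jxp_periax_width_nm = 8,
    ind_periax_width_nm = 8,
    n_lamellae          = 15L,
    # axial cross-section areas of the peri-axonal diffusion path (um^2);
    # numerically ~ pi * diameter * width but set independently
    axial_area_ind_um2  = 0.02,
    axial_area_jxp_um2  = 0.02,
    axial_area_pnj_um2  = 0.004,
    # radial diffusion area from the node shell to the bath (um^2)
    radial_area_node_um2 = 2.2,
    # thickness of the extracellular shell tracked outside each node (nm);
    # not a printed constant -- the fast 2.2 um^2 radial path keeps nodal
    # [K+]o pinned near bath regardless of this width
    node_shell_width_nm = 30
  )
}

section_kinds <- c("NODE", "PNJ", "JXP", "IND")

#' Build the discretized morphology of one myelinated axon
#'
#' Constructs the ordered section list (repeating pattern
#' \code{NODE, (PNJ, JXP, IND, JXP, PNJ) x 20, NODE}; 121 sections in all),
#' subdivides sections into compartments, and attaches peri-axonal geometry
#' (annular shell volumes and diffusion-link areas/distances).
#'
#' @param overrides Named list replacing entries of
#'   \code{\link{morphology_defaults}}. All geometric values must be positive.
#' @param nseg Named integer vector giving the number of equal compartments
#'   per section kind. The long (83 um) internode section is subdivided by
#'   default for spatial accuracy.
#' @return An object of class \code{axon_morphology}: list with
#'   \code{sections} (one row per section), \code{compartments} (one row per
#'   compartment, with centre positions, membrane areas and peri-axonal shell
#'   volumes), \code{node_centers} (21 axial positions, um),
#'   \code{diffusion_links} (see \code{\link{periaxonal_network}}), and
#'   \code{params}.
#' @examples
#' ax <- build_axon()
#' nrow(ax$sections)          # 121
#' max(ax$sections$axial_end) # 2001 um
#' @export
build_axon <- function(overrides = list(),
                       nseg = c(NODE = 1L, PNJ = 1L, JXP = 1L, IND = 4L)) {
  p <- morphology_defaults()
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(p))
    if (length(bad))
      stop("unknown morphology parameter(s): ", paste(bad, collapse = ", "))
    p[names(overrides)] <- overrides
  }
  num <- vapply(p, is.numeric, logical(1))
  for (nm in names(p)[num]) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("morphology parameter '", nm, "' must be positive and finite")
  }
  nseg <- nseg[section_kinds]
  if (any(is.na(nseg)) || any(nseg < 1L))
    stop("nseg must give a positive compartment count for NODE, PNJ, JXP, IND")

  ni <- as.integer(p$n_internodes)
  half <- data.frame(
    kind   = c("PNJ", "JXP", "IND"),
    length = c(p$pnj_length_um, p$jxp_length_um, p$ind_length_um / 2),
    diam   = c(p$pnj_diam_um, p$jxp_diam_um, p$ind_diam_um),
    width_nm = c(p$pnj_periax_width_nm, p$jxp_periax_width_nm,
                 p$ind_periax_width_nm),
    stringsAsFactors = FALSE
  )
  node_row <- data.frame(kind = "NODE", length = p$node_length_um,
                         diam = p$node_diam_um,
                         width_nm = p$node_shell_width_nm,
                         stringsAsFactors = FALSE)
  internode <- rbind(half, half[rev(seq_len(nrow(half))), ])
  # merge the two IND halves into one geometric section of full length
  ind_full <- internode$kind == "IND"
  internode <- internode[-which(ind_full)[2], ]
  internode$length[internode$kind == "IND"] <- p$ind_length_um

  secs <- node_row
  for (k in seq_len(ni)) secs <- rbind(secs, internode, node_row)
  rownames(secs) <- NULL
  secs$lamellae <- ifelse(secs$kind == "NODE", 0L, as.integer(p$n_lamellae))
  secs$axial_start <- cumsum(c(0, secs$length[-nrow(secs)]))
  secs$axial_end <- secs$axial_start + secs$length
  secs$section <- seq_len(nrow(secs))

  # subdivide sections into compartments
  comp_list <- lapply(seq_len(nrow(secs)), function(i) {
    s <- secs[i, ]
    n <- nseg[[s$kind]]
    len <- s$length / n
    x0 <- s$axial_start + (seq_len(n) - 1) * len
    data.frame(section = s$section, kind = s$kind, length = len,
               diam = s$diam, width_nm = s$width_nm,
               x_start = x0, x_center = x0 + len / 2,
               stringsAsFactors = FALSE)
  })
  comp <- do.call(rbind, comp_list)
  comp$comp <- seq_len(nrow(comp))
  # axolemma membrane area and peri-axonal shell volume (thin annulus)
  comp$area_um2 <- pi * comp$diam * comp$length
  comp$volume_um3 <- pi * comp$diam * (comp$width_nm * 1e-3) * comp$length
  comp$node_index <- NA_integer_
  is_node <- comp$kind == "NODE"
  comp$node_index[is_node] <- seq_len(sum(is_node))

  morph <- structure(
    list(sections = secs,
         compartments = comp,
         node_centers = comp$x_center[is_node],
         params = p,
         nseg = nseg),
    class = "axon_morphology"
  )
  morph$diffusion_links <- periaxonal_network(morph)
  validate_morphology(morph)
  morph
}

validate_morphology <- function(m) {
  secs <- m$sections
  nn <- sum(secs$kind == "NODE")
  if (nn != m$params$n_internodes + 1L)
    stop("expected ", m$params$n_internodes + 1L, " nodes, found ", nn)
  stopifnot(all(secs$length > 0), all(secs$diam > 0),
            all(m$compartments$volume_um3 > 0))
  invisible(m)
}

#' Peri-axonal potassium diffusion network
#'
#' Builds the Fickian diffusion links of the peri-axonal space: an axial
#' chain IND-IND-JXP-PNJ-node shell within each half-internode (the two IND
#' halves of an internode are continuous at its midpoint), plus one radial
#' link from every node shell to the bath (an infinite reservoir at the bath
#' concentration). Axial link areas follow the per-section-kind diffusion
#' areas; a link between unlike kinds takes the smaller (bottleneck) area, so
#' the PNJ-to-node-shell link has the PNJ area. Link distances are
#' centre-to-centre; the bath link distance is half the node-shell width.
#'
#' @param morph An \code{axon_morphology} (the links are also precomputed and
#'   stored in it by \code{\link{build_axon}}).
#' @param node_shell_width_nm Optional override of the node shell thickness.
#' @return data.frame with columns \code{a}, \code{b} (compartment indices;
#'   \code{b = 0} denotes BATH), \code{area_um2}, \code{dx_um}.
#' @export
periaxonal_network <- function(morph, node_shell_width_nm = NULL) {
  comp <- morph$compartments
  p <- morph$params
  shell_nm <- if (is.null(node_shell_width_nm)) p$node_shell_width_nm else
    node_shell_width_nm
  if (shell_nm <= 0) stop("node_shell_width_nm must be positive")

  ax_area <- c(NODE = Inf,  # node shell is not an axial bottleneck
               PNJ = p$axial_area_pnj_um2,
               JXP = p$axial_area_jxp_um2,
               IND = p$axial_area_ind_um2)
  n <- nrow(comp)
  a <- seq_len(n - 1); b <- a + 1L
  links <- data.frame(
    a = a, b = b,
    area_um2 = pmin(ax_area[comp$kind[a]], ax_area[comp$kind[b]]),
    dx_um = comp$x_center[b] - comp$x_center[a],
    row.names = NULL
  )
  nodes <- which(comp$kind == "NODE")
  bath <- data.frame(a = nodes, b = 0L,
                     area_um2 = p$radial_area_node_um2,
                     dx_um = (shell_nm * 1e-3) / 2)
  rbind(links, bath)
}

#' @export
print.axon_morphology <- function(x, ...) {
  cat("Myelinated axon morphology\n")
  cat(sprintf("  sections: %d (%d nodes, %d internode parts)\n",
              nrow(x$sections), sum(x$sections$kind == "NODE"),
              x$params$n_internodes))
  cat(sprintf("  compartments: %d; total length: %g um\n",
              nrow(x$compartments), max(x$sections$axial_end)))
  cat(sprintf("  node spacing: %g um; myelin lamellae: %d\n",
              diff(x$node_centers)[1], x$params$n_lamellae))
  invisible(x)
}

#' Write / read a morphology section table
#'
#' Plain tab-separated dump of the section list (kind, length, diameter,
#' peri-axonal width, lamellae) for inspection and testing.
#'
#' @param morph An \code{axon_morphology}.
#' @param path File path.
#' @return \code{write_morphology} returns \code{path} invisibly;
#'   \code{read_morphology_table} returns the section data.frame.
#' @export
write_morphology <- function(morph, path) {
  tab <- morph$sections[, c("section", "kind", "length", "diam",
                            "width_nm", "lamellae")]
  names(tab) <- c("section", "kind", "length_um", "diameter_um",
                  "periaxonal_width_nm", "lamellae")
  tab$periaxonal_width_nm[tab$kind == "NODE"] <- NA
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_morphology
#' @export
read_morphology_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
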