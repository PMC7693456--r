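#' Salience-network node atlas
#'
#' Constructs the default 19-node salience-network (SN) atlas used throughout
#' the package: 7 anterior and 12 posterior nodes with MNI millimetre
#' coordinates where published. Node order is fixed and defines the row and
#' column order of every connectivity matrix. Two template nodes have no
#' published coordinates; their coordinates are stored as \code{NA}.
#'
#' @return An object of class \code{sn_atlas}: a data frame with columns
#'   \code{node_id}, \code{label}, \code{subnetwork} (\code{"anterior"} or
#'   \code{"posterior"}) and MNI coordinates \code{x}, \code{y}, \code{z}
#'   (mm; \code{NA} where the template does not publish them).
#' @examples
#' atlas <- sn_atlas()
#' table(atlas$subnetwork)
#' @export
sn_atlas <- function() {
  nodes <- rbind(
    # anterior subnetwork (7 nodes)
    data.frame(label = "dACC",               subnetwork = "anterior", x =   0, y =  16, z =  46),
    data.frame(label = "anterior_insula_L",  subnetwork = "anterior", x = -40, y =  14, z =  -4),
    data.frame(label = "anterior_insula_R",  subnetwork = "anterior", x =  42, y =  14, z =  -2),
    data.frame(label = "frontal_mid_L",      subnetwork = "anterior", x = -32, y =  46, z =  22),
    data.frame(label = "frontal_mid_L2",     subnetwork = "anterior", x = -40, y =  36, z =  32),
    data.frame(label = "frontal_mid_R",      subnetwork = "anterior", x =  28, y =  46, z =  26),
    data.frame(label = "frontal_mid_R2",     subnetwork = "anterior", x =  NA, y =  NA, z =  NA),
    # posterior subnetwork (12 nodes)
    data.frame(label = "posterior_insula_L", subnetwork = "posterior", x = -36, y = -14, z =  -6),
    data.frame(label = "posterior_insula_R", subnetwork = "posterior", x =  40, y =  -6, z =  -8),
    data.frame(label = "supramarginal_L",    subnetwork = "posterior", x = -58, y = -38, z =  36),
    data.frame(label = "supramarginal_R",    subnetwork = "posterior", x =  62, y = -32, z =  42),
    data.frame(label = "cingulum_mid_R",     subnetwork = "posterior", x =  12, y = -28, z =  44),
    data.frame(label = "precuneus_L",        subnetwork = "posterior", x =  -8, y = -52, z =  60),
    data.frame(label = "thalamus_L",         subnetwork = "posterior", x = -12, y = -22, z =   6),
    data.frame(label = "thalamus_R",         subnetwork = "posterior", x =  12, y = -14, z =  10),
    data.frame(label = "cerebellum_6_L",     subnetwork = "posterior", x = -34, y = -56, z = -32),
    data.frame(label = "cerebellum_6_L2",    subnetwork = "posterior", x = -34, y = -42, z = -38),
    data.frame(label = "cerebellum_6_R",     subnetwork = "posterior", x =  36, y = -42, z = -40),
    data.frame(label = "cerebellum_6_R2",    subnetwork = "posterior", x =  NA, y =  NA, z =  NA)
  )
  nodes <- cbind(node_id = seq_len(nrow(nodes)), nodes)
  validate_atlas(structure(nodes, class = c("sn_atlas", "data.frame")))
}

validate_atlas <- function(atlas) {
  stopifnot(is.data.frame(atlas))
  need <- c("node_id", "label", "subnetwork")
  if (!all(need %in% names(atlas)))
    stopf("atlas must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(atlas$label)) stopf("atlas labels must be unique")
  if (!all(atlas$subnetwork %in% c("anterior", "posterior")))
    stopf("subnetwork must be 'anterior' or 'posterior'")
  atlas
}

#' Read or write a node atlas as TSV
#'
#' @param path file path of a tab-separated atlas table with columns
#'   \code{node_id}, \code{label}, \code{subnetwork}, \code{x}, \code{y},
#'   \code{z}.
#' @return \code{read_atlas} returns an \code{sn_atlas};
#'   \code{write_atlas} returns \code{path} invisibly.
#' @export
read_atlas <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_atlas(structure(df, class = c("sn_atlas", "data.frame")))
}

#' @rdname read_atlas
#' @param atlas an \code{sn_atlas}
#' @export
write_atlas <- function(atlas, path) {
  utils::write.table(as.data.frame(atlas), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.sn_atlas <- function(x, ...) {
  cat(sprintf("SN atlas: %d nodes (%d anterior, %d posterior)\n",
              nrow(x), sum(x$subnetwork == "anterior"),
              sum(x$subnetwork == "posterior")))
  print.data.frame(x, ...)
  invisible(x)
}
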