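# Shared helpers for building small grids and hand-made orientation fields.

vg <- function(arr, spacing = c(1, 1, 1), origin = c(0, 0, 0))
  voxel_grid(arr, spacing_um = spacing, origin_um = origin)

# hand-built orientation field from component arrays
make_field <- function(vx, vy, vz, valid = NULL, spacing = c(1, 1, 1)) {
  dm <- dim(vx)
  if (is.null(valid)) valid <- array(TRUE, dm)
  structure(list(vx = vx, vy = vy, vz = vz, valid = valid,
                 spacing_um = spacing, origin_um = c(0, 0, 0),
                 axes = "RAS", dim = dm),
            class = "orientation_field")
}

# uniform unit-direction field
uniform_field <- function(dm, dir = c(1, 0, 0)) {
  dir <- dir / sqrt(sum(dir^2))
  make_field(array(dir[1], dm), array(dir[2], dm), array(dir[3], dm))
}

# small chain ontology: root -> A -> B -> ...
chain_ontology <- function(n) {
  ontology(data.frame(id = seq_len(n),
                      parent_id = c(NA, seq_len(n - 1))))
}

# streamline set from a list of matrices without validation ceremony
sl <- function(...) streamline_set(list(...))

# logical-mask grid sharing `ref`'s geometry
vg_mask <- function(ref, values) {
  voxel_grid(array(values, dim(ref$data)), spacing_um = ref$spacing_um,
             origin_um = ref$origin_um, axes = ref$axes)
}
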