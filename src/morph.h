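#ifndef CORTMORPH_MORPH_H
#define CORTMORPH_MORPH_H

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

// Column-major linear index for an nx x ny x nz grid.
inline R_xlen_t vox_idx(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// 6-neighbourhood offsets, axis-major: -x,+x,-y,+y,-z,+z
const int NB_AXIS[6] = {0, 0, 1, 1, 2, 2};
const int NB_SIGN[6] = {-1, +1, -1, +1, -1, +1};

// Squared Euclidean distance transform to a voxel set, anisotropic spacing.
// mask: nonzero marks the target set. Returns squared distances (mm^2).
// If feat is non-null it receives, for every voxel, the linear index of the
// nearest target voxel (feature transform).
void edt_squared(const int* mask, const int* dims, const double* spacing,
                 double* d2, R_xlen_t* feat);

#endif
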