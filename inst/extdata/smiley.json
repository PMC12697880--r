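{
  "width": 16,
  "height": 16,
  "n_types": 3,
  "types": [
    [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1],
    [1, 1, 1, 1, 1, 1, 2, 2, 2, 2, 1, 1, 1, 1, 1, 1],
    [1, 1, 1, 1, 2, 2, 2, 2, 2, 2, 2, 2, 1, 1, 1, 1],
    [1, 1, 1, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 1, 1, 1],
    [1, 1, 2, 2, 3, 3, 2, 2, 2, 2, 3, 3, 2, 2, 1, 1],
    [1, 1, 2, 2, 3, 3, 2, 2, 2, 2, 3, 3, 2, 2, 1, 1],
    [1, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 1],
    [1, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 1],
    [1, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 1],
    [1, 2, 2, 2, 3, 2, 2, 2, 2, 2, 2, 3, 2, 2, 2, 1],
    [1, 1, 2, 2, 2, 3, 3, 3, 3, 3, 3, 2, 2, 2, 1, 1],
    [1, 1, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 1, 1],
    [1, 1, 1, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 1, 1, 1],
    [1, 1, 1, 1, 2, 2, 2, 2, 2, 2, 2, 2, 1, 1, 1, 1],
    [1, 1, 1, 1, 1, 1, 2, 2, 2, 2, 1, 1, 1, 1, 1, 1],
    [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
  ],
  "organs": {
    "LeftEye": {
      "cells": [
        [4, 4],
        [5, 4],
        [4, 5],
        [5, 5]
      ],
      "boundary_cells": [
        [3, 3],
        [4, 3],
        [5, 3],
        [6, 3],
        [3, 4],
        [6, 4],
        [3, 5],
        [6, 5],
        [3, 6],
        [4, 6],
        [5, 6],
        [6, 6]
      ]
    },
    "RightEye": {
      "cells": [
        [4, 10],
        [5, 10],
        [4, 11],
        [5, 11]
      ],
      "boundary_cells": [
        [3, 9],
        [4, 9],
        [5, 9],
        [6, 9],
        [3, 10],
        [6, 10],
        [3, 11],
        [6, 11],
        [3, 12],
        [4, 12],
        [5, 12],
        [6, 12]
      ]
    },
    "Mouth": {
      "cells": [
        [9, 4],
        [10, 5],
        [10, 6],
        [10, 7],
        [10, 8],
        [10, 9],
        [10, 10],
        [9, 11]
      ],
      "boundary_cells": [
        [8, 3],
        [9, 3],
        [10, 3],
        [8, 4],
        [10, 4],
        [11, 4],
        [8, 5],
        [9, 5],
        [11, 5],
        [9, 6],
        [11, 6],
        [9, 7],
        [11, 7],
        [9, 8],
        [11, 8],
        [9, 9],
        [11, 9],
        [8, 10],
        [9, 10],
        [11, 10],
        [8, 11],
        [10, 11],
        [11, 11],
        [8, 12],
        [9, 12],
        [10, 12]
      ]
    }
  }
}
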