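# Published best configuration: unbalanced vs. stable node (values as
# printed; note the units list has 9 entries for 11 declared layers, with
# two entries outside the searchable [1, 64] range).
node: unbalanced_vs_stable
n_dense_layers: 11
units: [32, 4, 38, 5034, 38, 22, 624, 58, 58]
activations: [tanh, tanh, selu, tanh, tanh, tanh, selu, tanh, selu, tanh, selu]
use_conv: true
conv_filters: 6
conv_window: 4
conv_activation: sigmoid
use_pooling: true
use_lstm: false
learning_rate: 0.001
optimizer: adam
batch_size: 19
window_length: 16
channels: [P0, P6, P9, P11, P12, P13, P15, A0]
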