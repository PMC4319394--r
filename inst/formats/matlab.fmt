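# MATLAB export format
name = matlab
comment = %
assign = =
terminator = ;
index_base = 1
block_style = matlab
piecewise = call
bool.true = true
bool.false = false
pi = pi
nan = NaN
array.constants = CONSTANTS({i})
array.states = STATES({i})
array.rates = RATES({i})
array.algebraic = ALGEBRAIC({i})
scalar.voi = VOI
op.plus = infix +
op.minus = infix -
op.times = infix *
op.divide = infix /
op.power = infix ^
op.root = call sqrt
op.exp = call exp
op.ln = call log
op.log = call log10
op.abs = call abs
op.floor = call floor
op.ceiling = call ceil
op.sin = call sin
op.cos = call cos
op.tan = call tan
op.arcsin = call asin
op.arccos = call acos
op.arctan = call atan
op.and = infix &&
op.or = infix ||
op.not = prefix ~
op.eq = infix ==
op.neq = infix ~=
op.lt = infix <
op.leq = infix <=
op.gt = infix >
op.geq = infix >=
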