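# C export format
name = c
comment = //
assign = =
terminator = ;
index_base = 0
block_style = c
piecewise = ternary_c
bool.true = 1
bool.false = 0
pi = M_PI
nan = NAN
array.constants = CONSTANTS[{i}]
array.states = STATES[{i}]
array.rates = RATES[{i}]
array.algebraic = ALGEBRAIC[{i}]
scalar.voi = voi
op.plus = infix +
op.minus = infix -
op.times = infix *
op.divide = infix /
op.power = call pow
op.root = call sqrt
op.exp = call exp
op.ln = call log
op.log = call log10
op.abs = call fabs
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
op.not = prefix !
op.eq = infix ==
op.neq = infix !=
op.lt = infix <
op.leq = infix <=
op.gt = infix >
op.geq = infix >=
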