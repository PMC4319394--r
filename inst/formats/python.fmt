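# Python export format
name = python
comment = #
assign = =
terminator =
index_base = 0
block_style = python
piecewise = ternary_python
bool.true = True
bool.false = False
pi = pi
nan = float('nan')
array.constants = constants[{i}]
array.states = states[{i}]
array.rates = rates[{i}]
array.algebraic = algebraic[{i}]
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
op.and = infix and
op.or = infix or
op.not = prefix not
op.eq = infix ==
op.neq = infix !=
op.lt = infix <
op.leq = infix <=
op.gt = infix >
op.geq = infix >=
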