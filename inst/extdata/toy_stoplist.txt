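# toy function-word stoplist
the
a
an
and
or
but
of
to
in
on
at
was
were
is
are
i
we
my
all
that
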